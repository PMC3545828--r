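Package: ddpipesim
Title: Monte Carlo Simulation of the Early Drug-Discovery Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates discrete virtual drug-discovery projects progressing
    through the milestone system of early pharmaceutical research (exploratory
    ideation, hit-to-lead, lead optimization, preclinical development) under
    stochastic go/no-go decisions, dynamic chemist/biologist staffing with
    priority-driven reassignment, group-size-dependent full-time-equivalent
    (FTE) efficiency, DMPK support of lead optimization, and optional project
    lifetime cutoffs. Provides a tab-delimited control-file interface, staffing
    and efficiency parameter sweeps with difference maps and frontier
    extraction, an empirical biphasic (double-logistic) frontier fit, and a
    command-line driver, so that productivity surfaces (preclinical candidates
    per year) can be explored for a given portfolio of project types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
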