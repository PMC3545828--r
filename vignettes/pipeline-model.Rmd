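---
title: "A Monte Carlo model of the early drug-discovery pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Monte Carlo model of the early drug-discovery pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddpipesim)
```

## The model

`ddpipesim` simulates a *working group* — a cross-functional department of
medicinal chemists and biologists, with drug metabolism/pharmacokinetics
(DMPK) support — running a portfolio of discovery projects through the
early-pipeline milestone system:

    exploratory  →  hit to lead (HTL)  →  lead optimization (LO)  →  preclinical development (PD)

Each transition is a stochastic go/no-go gate: a uniform draw `r` in [0, 1)
succeeds when it falls below the user-set success probability for that
milestone (the defaults, 0.80 / 0.75 / 0.85, are literature-reported attrition
benchmarks for the three discovery transitions). Entry into preclinical
development is the absorbing success state; the productivity metric is the
mean number of preclinical candidates (PC) per year.

Projects are discrete and individually staffed. Three project types differ
only in their hit-to-lead staffing targets: chemistry-driven (default 2
chemists + 3 biologists), biology/HTS-driven (1 + 3), and follow-on (back-up)
series (2 + 1). Every lead-optimization campaign has the same targets
(default 4 + 4). The time to the next milestone decision for a project with
`C` chemists and `B` biologists assigned out of targets `TC`/`TB` is

$$A \;=\; \frac{CT \, (TC + TB)}{F\,(C + B)},$$

where `CT` is the target cycle time (18 months HTL→LO, 24 months LO→PD) and
`F` is the FTE efficiency (below). Cycle time is thus linear in inverse
effective staffing — a half-staffed team takes twice as long, and two
scientists at 50% efficiency equal one at 100%. When staffing or DMPK support
changes mid-stage, the clock is rescaled so the completed fraction of the
stage is preserved. An important consequence used throughout this vignette:
the *total* effective effort a stage consumes, $F \times$ person-months
$= CT\,(TC+TB)$, is invariant to how the staffing unfolds over time. Output
is therefore effort-limited, and the simulator's behaviour can be
cross-checked against closed-form effort budgets.

### FTE efficiency

FTE efficiency is the fraction of a scientist's time spent on direct project
work rather than coordination overhead, which grows with working-group size
`x`. It follows a reversed logistic,

$$E(x) \;=\; \frac{1}{1 + e^{x/A - B}}
       \;=\; \frac{1}{1 + e^{1.1 (x - M)/(M - N)}},$$

parameterised by the interpretable anchors `M` (group size at 50% efficiency,
default 40) and `N` (size at 75%, default 20; `M > N` always). The constant
1.1 approximates $\ln 3$; we keep it literally, so $E(N) = 0.7503$ rather
than exactly 0.75 — the package's tests document this 0.0003 discrepancy
rather than hiding it. Efficiency is evaluated once per run at the total
working-group size `n_chemists + n_biologists`; a static
`efficiency_override` bypasses the curve entirely. The same `F` discounts
every clock in the model, including exploratory ideation effort, which keeps
the "two at 50% equal one at 100%" identity global.

### Staffing dynamics

A new hit-to-lead project is created staffed by one chemist and one
biologist. The same draw `r` that carried it through the exploratory gate is
its priority, which caps per-discipline staffing at
$\lceil r \cdot s / t \rceil$ (target `s`, gate threshold `t`; a draw of
exactly zero pins the project at its default staffing). Because a surviving
project has `r < t`, the cap never exceeds the target.

Scientists freed by a termination, a completed campaign, or a hold are
reassigned every month in a fixed priority order: (1) understaffed
lead-optimization projects, (2) hit-to-lead projects on hold, (3) understaffed
active hit-to-lead projects (respecting their caps), (4) exploratory
ideation. Within a tier, the least-supported project (lowest staffed
fraction) is filled first; ties break toward the older stage entry, then the
lower project id, so scheduling is deterministic given the random stream.

A lead-optimization campaign is designated *high priority* with probability
`pct_high_priority_lo` at stage entry. High-priority campaigns are staffed to
target immediately: free (exploratory) scientists are taken first, then
hit-to-lead projects are drained starting with the least supported. What
happens to the drained project is governed by `raid_mode`. The default,
`"terminate"`, kills it; the alternative, `"hold"`, suspends it with its
progress frozen (it keeps aging toward any lifetime cutoff) for tier-2
re-staffing. We chose termination as the default after measuring both: under
`"hold"`, an all-high-priority portfolio without lifetime cutoffs loses
essentially nothing (a held project just resumes later), which erases the
sizable penalty for consistently raiding early projects that the priority
mechanism exists to express; under `"terminate"` that penalty (about −20% at
the default configuration) appears as intended. Standard-priority campaigns
keep their hit-to-lead staffing and grow only as scientists free up.

### Exploratory ideation and spawning

The model assumes an excess of ideas relative to scientists, so exploratory
work is not tracked as discrete projects. Instead, every free scientist
accrues `F`-weighted exploratory effort monthly; each
`2 * exploratory_cycle_months` person-months of accrued effort funds one
exploratory gate roll, and a success becomes a hit-to-lead project if a free
chemist + biologist pair is available to seed it (otherwise the accrual
waits). `exploratory_cycle_months` is the engine's only free parameter — the
attempt rate is not observable — and was calibrated once: sweeping it at the
reference configuration (18 + 18 scientists, default parameters) shows output
saturating below ~6 months, at about 0.655 PC/yr; we froze the default at 6
months (one attempt costs 12 F-weighted person-months of
validation/screening work, a scientifically plausible figure) and never
revisited it. See "Limitations" for why the saturation level, not the
parameter, bounds the headline output.

### DMPK, cutoffs, and the monthly step

Up to `dmpk_capacity` lead-optimization campaigns concurrently hold DMPK
support, assigned in stage-entry (first-in-first-out) order; support
multiplies the remaining timeline by `1 - dmpk_impact` (default 0.9) and
frees its slot when the campaign ends. Optional lifetime cutoffs terminate
hit-to-lead or lead-optimization projects whose wall-clock stage age exceeds
`htl_lifetime_cutoff` / `lo_lifetime_cutoff` months (42/54 in the published
cutoff experiments); time on hold counts toward the age, since the cutoff
models organizational patience, not effort.

Time advances in 1-month steps with real-valued clocks; a decision fires when
a project's time-to-decision reaches zero. The step order is: advance clocks
→ enforce cutoffs → gate due projects → allocate DMPK → reassign → spawn.
Headcount conservation per discipline is asserted at every step boundary, an
invariant that caught a genuine scheduling bug during development (a raid
terminating a project already queued for its gate in the same month).

## Run control, seeds, and experiment design

A replicate simulates `warmup_years` (default 10) plus `collection_years`
(default 25) from an all-exploratory start; the warm-up transient is
discarded. Replicate seeds, and the seed of every sweep cell, are derived
from a base seed and the cell's axis *values* with a small congruential
hash, so any subgrid, reordering, or direct rerun of a cell reproduces it
bit-for-bit. The package's grid experiments (`sweep_staff_grid`,
`sweep_efficiency`, `sweep_project_mix`, `sweep_team_size`) are plain loops
over replicated runs plus labelled matrices; `difference_map` and
`frontier_diagonal` post-process them. Efficiency sweeps blank cells with
`M < N + 10`, where the logistic would be implausibly steep.

The equal-staffing diagonal of a productivity surface is biphasic — rising to
a plateau, then falling where efficiency losses dominate — and can be
summarised by a double-logistic fit (`fit_biphasic`). The conventional
9-parameter form of that curve is redundant: the offsets and shifts enter
only through the products $B_{up}e^{-D_{up}}$ and $B_{dn}e^{D_{dn}}$, so only
7 combinations are identifiable. The fitter uses damped Levenberg–Marquardt,
which tolerates the flat ridge, and reports the identifiable products
alongside the familiar coordinates; its self-test asserts recovery of the
identifiable quantities and of the curve, not of the redundant raw vector.

A worked example at desk scale:

```{r example, eval = FALSE}
p <- default_parameters()              # 18 chemists + 18 biologists
run <- run_pipeline(p, base_seed = 1, n_replicates = 50)
run$mean_pc                            # ~0.66 preclinical candidates/year

sw <- sweep_staff_grid(p, seq(3, 30, 3), seq(3, 30, 3), base_seed = 1,
                       n_replicates = 20)
frontier_diagonal(sw)                  # peaks near 18 + 18 scientists
```

Problem sizes used by the bundled acceptance script (`scripts/acceptance.R`)
are 15 collection years after a 10-year warm-up, 20 replicates per sweep
cell and 50 for single-configuration scenarios, with stride-3 staffing
diagonals and stride-6 grids; these reproduce the qualitative results
stably (the staffing optimum in particular is invariant across seeds) while
keeping a full recomputation around a minute on one core.

## What the synthetic world does and does not contain

All inputs are parametric; there is no external data. The generator
reproduces the structural features the model is about — milestone attrition,
integer team assembly per discipline, priority raids, group-size-dependent
efficiency, clustered candidate arrivals — and deliberately omits features of
real portfolios: project-to-project heterogeneity in cycle times and success
probabilities beyond type, inter-project scientific correlation (a target
family failing together), attrition mid-stage (all failures occur at
decision points), hiring/attrition of scientists, and any economics. Passing
tests therefore validate the scheduling and accounting machinery and the
qualitative response surfaces, not calibration to any particular
organization's data.

## Numerical choices

* Clocks are real-valued; gates fire on the first monthly boundary at which
  the time-to-decision is ≤ 0 (tolerance 1e-9), so corrected cycle times are
  effectively rounded up to whole months.
* Exploratory accrual uses the same tolerance when testing whether a slot's
  effort has been banked.
* `staff_cap` uses exact `ceiling`; the `r = 0` edge collapses to the default
  single scientist per discipline.
* Ties in "least supported" break by stage-entry month, then project id —
  scheduling is a deterministic function of the random stream.
* The logistic efficiency underflows to numerical zero for group sizes many
  times `M` at steep settings; sweeps keep `M ≥ N + 10`, where the curve is
  well-behaved over any realistic group.

## Known limitations

* **Headline level vs. effort ceiling.** With efficiency evaluated at the
  total group size (the reading consistent with a staffing optimum near 36
  scientists and a plateau beyond it), the invariant effort budget per
  candidate caps output at the reference configuration near 0.70 PC/yr; the
  calibration therefore saturates at ~0.66 rather than the ~0.86 sometimes
  quoted for comparable setups, and we report the model's own number. The
  alternative reading (efficiency at per-discipline size) would raise the
  level but abolish the optimum; it is not available as a switch because the
  two readings change every surface in the package.
* **Follow-on portfolios.** Cheaper follow-on teams spawn more
  lead-optimization campaigns than a fixed group can staff; under the
  reassignment rules (standard-priority campaigns can draw only free
  scientists) the marginal campaigns crawl and, with cutoffs active, waste
  effort. All-follow-on portfolios consequently score slightly below the
  mixed baseline here, rather than above it.
* Lead-optimization staffing shortfalls are persistent by design: nothing
  short of a high-priority raid moves a scientist off a live hit-to-lead
  project.
* One working group only; inter-group resource sharing and the downstream
  clinical pipeline are out of scope.
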