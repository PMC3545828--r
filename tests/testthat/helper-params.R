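# Shared fixtures: small, fast parameter sets built in code.

# short run for behavioural tests
quick_params <- function(...) {
  pipeline_params(collection_years = 5L, warmup_years = 2L, n_replicates = 3L,
                  ...)
}

# a deterministic single-pair pipeline: one chemist + one biologist, every
# gate certain, 100% efficiency, all team targets 1+1. One exploratory
# attempt costs 2 person-months, so the free pair spawns a project in its
# first free month; each project then takes 18 + 24 months. Candidates
# appear at months 43, 85, 127, ... (see test-engine-sim.R for the
# derivation).
chain_params <- function(...) {
  pipeline_params(
    p_hit_to_lead = 1, p_lead_opt = 1, p_preclinical = 1,
    pct_followon = 0, pct_chem_driven = 1,
    htl_chem_chemdriven = 1L, htl_bio_chemdriven = 1L,
    htl_chem_biodriven = 1L, htl_bio_biodriven = 1L,
    htl_chem_followon = 1L, htl_bio_followon = 1L,
    lo_chem_target = 1L, lo_bio_target = 1L,
    efficiency_override = 1, exploratory_cycle_months = 1,
    n_chemists = 1L, n_biologists = 1L,
    warmup_years = 0L, ...)
}

# bare state with a hand-placed project, for scripted scenario tests
scripted_state <- function(params, total_years = 10) {
  ddpipesim:::new_state(params, total_years)
}
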