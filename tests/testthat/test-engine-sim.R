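test_that("a replicate is fully reproducible from its seed", {
  p <- quick_params(collection_years = 15L)
  a <- run_replicate(p, 77)
  b <- run_replicate(p, 77)
  expect_identical(a, b)
  c <- run_replicate(p, 78)
  expect_false(identical(a$annual_pc, c$annual_pc))
})

test_that("nothing ever succeeds when every gate is certain to fail", {
  p <- quick_params(p_hit_to_lead = 0, p_lead_opt = 0, p_preclinical = 0)
  r <- run_replicate(p, 1)
  expect_identical(r$annual_pc, rep(0L, p$collection_years))
  expect_equal(r$mean_pc, 0)
})

test_that("the single-pair deterministic chain matches the closed-form schedule", {
  # 1 chemist + 1 biologist, all gates certain, 100% efficiency, all targets
  # 1+1, exploratory cycle 1 month. The free pair accrues 2 person-months in
  # month 1 and spawns a project (clock 18 * 2 / 2 = 18 months). The project
  # gates to lead optimization when its clock reaches zero at month 19, runs
  # a 24-month campaign, and delivers the candidate at month 43; the freed
  # pair re-spawns the same month, so candidates land at months 43 + 42k.
  p <- chain_params(collection_years = 30L)
  r <- run_replicate(p, 123)
  pc_months <- seq(43, 360, by = 42)
  expected <- tabulate((pc_months - 1) %/% 12 + 1, nbins = 30)
  expect_identical(r$annual_pc, as.integer(expected))
  expect_identical(sum(r$annual_pc), 8L)
  expect_identical(unname(r$terminations), rep(0L, 5))
  # the all-certain limit is seed-independent
  expect_identical(run_replicate(p, 99)$annual_pc, r$annual_pc)
})

test_that("an isolated lead-optimization project delivers at the corrected cycle time", {
  p <- chain_params(collection_years = 10L, n_chemists = 1L, n_biologists = 1L)
  st <- scripted_state(p)
  ddpipesim:::add_project(st, stage = 2L, type = 1L, r = 0.5, C = 1L, B = 1L,
                          TC = 1L, TB = 1L, capC = 1L, capB = 1L)
  st$free_c <- 0L; st$free_b <- 0L   # the pair sits on the project
  # A = 24 * 2 / (1 * 2) = 24: the candidate must appear exactly then
  for (m in 1:24) ddpipesim:::step_state(st)
  expect_equal(sum(st$pc_by_year), 1)
  expect_equal(st$month, 24L)
  # and not a month before
  st2 <- scripted_state(p)
  ddpipesim:::add_project(st2, stage = 2L, type = 1L, r = 0.5, C = 1L, B = 1L,
                          TC = 1L, TB = 1L, capC = 1L, capB = 1L)
  st2$free_c <- 0L; st2$free_b <- 0L
  for (m in 1:23) ddpipesim:::step_state(st2)
  expect_equal(sum(st2$pc_by_year), 0)
})

test_that("an understaffed project takes target/k times its cycle time", {
  # 1+1 staffed out of 2+2 targets, caps pinned at 1, full efficiency:
  # clock = 18 * 4 / 2 = 36 months to the hit-to-lead gate
  p <- chain_params(collection_years = 10L, n_chemists = 1L, n_biologists = 1L)
  st <- scripted_state(p)
  i <- ddpipesim:::add_project(st, stage = 1L, type = 1L, r = 0, C = 1L,
                               B = 1L, TC = 2L, TB = 2L, capC = 1L, capB = 1L)
  st$free_c <- 0L; st$free_b <- 0L   # nobody left to top the project up
  months_to_lo <- 0
  while (st$stage[i] == 1L && months_to_lo < 60) {
    ddpipesim:::step_state(st)
    months_to_lo <- months_to_lo + 1
  }
  expect_lte(abs(months_to_lo - 36), 1)
})

test_that("headcounts are conserved and caps respected every month", {
  for (seed in 1:3) {
    p <- pipeline_params(collection_years = 8L, warmup_years = 2L,
                         pct_high_priority_lo = 0.5,
                         htl_lifetime_cutoff = 42, lo_lifetime_cutoff = 54,
                         dmpk_capacity = 2L)
    r <- run_replicate(p, seed, keep_monthly = TRUE)   # step_state() also
    m <- r$monthly                                     # asserts internally
    expect_true(all(m[, "free_c"] + m[, "assigned_c"] == p$n_chemists))
    expect_true(all(m[, "free_b"] + m[, "assigned_b"] == p$n_biologists))
    expect_true(all(m[, "caps_ok"] == 1))
    expect_true(all(m[, "free_c"] >= 0 & m[, "free_b"] >= 0))
  }
})

test_that("more generous gates never lower mean output (common random numbers)", {
  base <- pipeline_params(collection_years = 10L, warmup_years = 3L)
  probs <- c(0.55, 0.75, 0.95)
  for (field in c("p_hit_to_lead", "p_lead_opt", "p_preclinical")) {
    means <- sapply(probs, function(q) {
      p <- base; p[[field]] <- q
      mean(sapply(1:20, function(i) run_replicate(p, derive_seed(7, i))$mean_pc))
    })
    sds <- 0.04  # ~sd of a 20-replicate mean here
    expect_true(all(diff(means) > -sds),
                info = sprintf("%s: %s", field, paste(round(means, 3),
                                                      collapse = " -> ")))
  }
})

test_that("lifetime cutoffs terminate overdue projects and only fire when set", {
  # no cutoffs: tallies stay zero
  r <- run_replicate(quick_params(), 5)
  expect_identical(unname(r$terminations[c("cutoff_htl", "cutoff_lo")]),
                   c(0L, 0L))
  # a 1+1-staffed project with targets 2+2 has a 36-month clock under full
  # efficiency; a 30-month hit-to-lead cutoff must kill it at month 31
  p <- chain_params(collection_years = 10L, n_chemists = 1L, n_biologists = 1L,
                    htl_lifetime_cutoff = 30, p_hit_to_lead = 0)
  st <- scripted_state(p)
  i <- ddpipesim:::add_project(st, stage = 1L, type = 1L, r = 0, C = 1L,
                               B = 1L, TC = 2L, TB = 2L, capC = 1L, capB = 1L)
  st$free_c <- 0L; st$free_b <- 0L
  for (m in 1:30) ddpipesim:::step_state(st)
  expect_true(st$alive[i])
  ddpipesim:::step_state(st)
  expect_false(st$alive[i])
  expect_equal(unname(st$term["cutoff_htl"]), 1L)
  expect_equal(st$free_c, 1L)        # scientist returned to the pool
  # fully staffed projects at full efficiency never reach the default cutoffs
  p2 <- chain_params(collection_years = 15L, htl_lifetime_cutoff = 42,
                     lo_lifetime_cutoff = 54)
  r2 <- run_replicate(p2, 1)
  expect_identical(unname(r2$terminations[c("cutoff_htl", "cutoff_lo")]),
                   c(0L, 0L))
  expect_gt(sum(r2$annual_pc), 0)
})

test_that("DMPK support is capacity-limited, FIFO, and shortens the clock", {
  p <- pipeline_params(dmpk_capacity = 1L, dmpk_impact = 0.1,
                       collection_years = 5L, warmup_years = 0L,
                       efficiency_override = 1)
  st <- scripted_state(p)
  first <- ddpipesim:::add_project(st, stage = 2L, type = 1L, r = 0.5, C = 4L,
                                   B = 4L, TC = 4L, TB = 4L, capC = 4L,
                                   capB = 4L, entry = 0L)
  st$month <- 1L   # second project enters a month later
  second <- ddpipesim:::add_project(st, stage = 2L, type = 1L, r = 0.5, C = 4L,
                                    B = 4L, TC = 4L, TB = 4L, capC = 4L,
                                    capB = 4L, entry = 1L)
  st$month <- 0L
  st$free_c <- st$free_c - 8L; st$free_b <- st$free_b - 8L
  ddpipesim:::step_state(st)
  expect_true(st$dmpk[first])        # FIFO by stage entry
  expect_false(st$dmpk[second])
  expect_equal(st$dmpk_used, 1L)
  # supported project: 24-month clock compressed by 10%
  expect_equal(st$A[first], 24 * 0.9)
  expect_equal(st$A[second], 24)
  # capacity 0 supports nobody
  p0 <- quick_params()
  r <- run_replicate(p0, 3, keep_monthly = TRUE)
  expect_equal(p0$dmpk_capacity, 0L)
})

test_that("high-priority raids drain the least-supported projects first", {
  p <- pipeline_params(pct_high_priority_lo = 1, p_lead_opt = 1,
                       raid_mode = "terminate", collection_years = 5L,
                       warmup_years = 0L, efficiency_override = 1,
                       n_chemists = 4L, n_biologists = 5L)
  st <- scripted_state(p)
  # due project about to transition to lead optimization (targets 4+4)
  due <- ddpipesim:::add_project(st, stage = 1L, type = 1L, r = 0.5, C = 1L,
                                 B = 1L, TC = 2L, TB = 3L, capC = 2L,
                                 capB = 2L, entry = 0L)
  # two bystanders: lean (staffed 2/5) and fat (staffed 4/5)
  lean <- ddpipesim:::add_project(st, stage = 1L, type = 2L, r = 0.5, C = 1L,
                                  B = 1L, TC = 2L, TB = 3L, capC = 2L,
                                  capB = 3L, entry = 0L)
  fat <- ddpipesim:::add_project(st, stage = 1L, type = 2L, r = 0.5, C = 1L,
                                 B = 3L, TC = 2L, TB = 3L, capC = 2L,
                                 capB = 3L, entry = 0L)
  st$free_c <- 1L; st$free_b <- 0L     # one free chemist, nothing else
  st$TD[due] <- 1                       # decision due next step
  ddpipesim:::step_state(st)
  expect_equal(st$stage[due], 2L)
  expect_true(st$hi[due])
  # free chemist taken first, then the lean project terminated, then the fat
  expect_false(st$alive[lean])
  expect_false(st$alive[fat])
  expect_equal(unname(st$term["raided"]), 2L)
  # raider filled to its 4+4 lead-optimization targets
  expect_equal(st$C[due], 4L)
  expect_equal(st$B[due], 4L)
  # hold mode parks the victim with its progress frozen, then re-staffs it
  # once scientists free up again
  p$raid_mode <- "hold"
  p$n_chemists <- 4L; p$n_biologists <- 4L
  st2 <- scripted_state(p)
  due2 <- ddpipesim:::add_project(st2, stage = 1L, type = 1L, r = 0.5, C = 1L,
                                  B = 1L, TC = 2L, TB = 3L, capC = 2L,
                                  capB = 2L, entry = 0L)
  lean2 <- ddpipesim:::add_project(st2, stage = 1L, type = 2L, r = 0.5, C = 1L,
                                   B = 1L, TC = 2L, TB = 3L, capC = 2L,
                                   capB = 3L, entry = 0L)
  st2$free_c <- 2L; st2$free_b <- 2L     # not enough to avoid the raid
  st2$TD[due2] <- 1
  te_before <- st2$TE[lean2] + 1          # clocks advance before the raid
  ddpipesim:::step_state(st2)
  expect_true(st2$alive[lean2])
  expect_true(st2$hold[lean2])
  expect_equal(st2$C[lean2] + st2$B[lean2], 0L)
  expect_equal(st2$TE[lean2], te_before)  # progress frozen while on hold
  # a scientist becomes available: the held project is tier-2 re-staffed
  st2$params$n_chemists <- 5L
  st2$free_c <- st2$free_c + 1L
  ddpipesim:::step_state(st2)
  expect_false(st2$hold[lean2])
  expect_gt(st2$C[lean2] + st2$B[lean2], 0L)
})

test_that("spawning needs both accrued effort and a free default pair", {
  # zero scientists: the state only ages
  p <- chain_params(collection_years = 2L, n_chemists = 0L, n_biologists = 0L)
  st <- scripted_state(p)
  for (m in 1:12) ddpipesim:::step_state(st)
  expect_equal(st$n, 0L)
  expect_equal(st$month, 12L)
  # a certain gate with one free pair and enough accrual: exactly one project
  p2 <- chain_params(collection_years = 2L)
  st2 <- scripted_state(p2)
  ddpipesim:::step_state(st2)
  expect_equal(st2$n, 1L)
  expect_equal(st2$stage[1], 1L)
  expect_equal(st2$C[1] + st2$B[1], 2L)   # default 1 chemist + 1 biologist
  expect_equal(st2$free_c + st2$free_b, 0L)
})

test_that("long-run spawn rate tracks mean free headcount", {
  # all gates fail at hit-to-lead entry, so every scientist stays free and
  # attempt bookkeeping is exact: attempts/month = F * headcount / (2 * ecm)
  p <- pipeline_params(p_hit_to_lead = 0, collection_years = 50L,
                       warmup_years = 0L, n_chemists = 6L, n_biologists = 6L,
                       efficiency_override = 0.5, exploratory_cycle_months = 6)
  r <- run_replicate(p, 11, log_events = TRUE)
  attempts <- sum(r$events$event == "exploratory_failed")
  expected <- 0.5 * 12 / (2 * 6) * 50 * 12    # = 0.5/mo * 600 months
  expect_equal(attempts, expected, tolerance = 0.02)
})

test_that("replicate aggregation is deterministic and mean-consistent", {
  p <- quick_params()
  agg <- run_pipeline(p, base_seed = 9, n_replicates = 4)
  expect_equal(agg$mean_pc, mean(agg$replicate_means))
  expect_identical(agg$replicates[[2]],
                   run_replicate(p, derive_seed(9, 2)))
  one <- run_pipeline(p, base_seed = 9, n_replicates = 1)
  expect_equal(one$mean_pc, one$replicates[[1]]$mean_pc)
  expect_true(is.na(one$sd_pc))
})

test_that("distinct base seeds give statistically indistinguishable means", {
  p <- pipeline_params(collection_years = 10L, warmup_years = 3L)
  a <- run_pipeline(p, base_seed = 1001, n_replicates = 20)$replicate_means
  b <- run_pipeline(p, base_seed = 2002, n_replicates = 20)$replicate_means
  expect_gt(t.test(a, b)$p.value, 0.01)
})

test_that("event logs record the lifecycle of every candidate", {
  p <- pipeline_params(collection_years = 12L, warmup_years = 0L)
  r <- run_replicate(p, 21, log_events = TRUE)
  ev <- r$events
  expect_true(all(c("month", "id", "event", "detail") %in% names(ev)))
  pcs <- ev[ev$event == "preclinical_candidate", ]
  expect_equal(nrow(pcs), sum(r$annual_pc))
  # every candidate was spawned and promoted before delivering
  for (id in pcs$id) {
    trail <- ev$event[ev$id == id & !is.na(ev$id)]
    expect_true(all(c("spawned", "htl_to_lo") %in% trail))
  }
})
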