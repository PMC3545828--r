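## Monte Carlo engine: discrete 1-month steps, real-valued project clocks.
## A project's state lives in parallel vectors inside an environment so that
## the monthly loop stays allocation-light; rosters are small (tens of
## projects) so per-step work is a handful of vectorised operations.

#' Roll a milestone go/no-go gate
#'
#' Draws one uniform number `r` in \[0, 1) and succeeds when `r` falls below
#' the milestone's success threshold. The draw is returned because, for the
#' exploratory -> hit-to-lead gate, the same number doubles as the new
#' project's priority and feeds the staffing ceiling of [staff_cap()].
#'
#' @param threshold milestone success probability in \[0, 1\].
#' @return `list(success = logical, r = numeric)`.
#' @export
#' @examples
#' set.seed(1); draw_gate(0.8)
draw_gate <- function(threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      is.na(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must be a probability in [0, 1]")
  r <- stats::runif(1)
  list(success = r < threshold, r = r)
}

#' Maximum staffing of a hit-to-lead project
#'
#' A hit-to-lead project's priority is the uniform draw `r` that carried it
#' through the exploratory gate with threshold `t`; its staffing ceiling per
#' discipline is `ceiling(r * s / t)` where `s` is the stage target for that
#' discipline. Because a successful project has `r < t` the ceiling never
#' exceeds the target. A draw of exactly zero restricts the project to the
#' default staffing of one scientist.
#'
#' @param r priority draw in \[0, 1).
#' @param s stage target (positive integer).
#' @param t exploratory gate threshold in (0, 1\].
#' @return Positive integer staffing ceiling.
#' @export
#' @examples
#' staff_cap(0.5, 3, 0.8)   # 2
staff_cap <- function(r, s, t) {
  if (any(t <= 0)) stop("threshold t must be positive")
  if (any(t > 1)) stop("threshold t must be <= 1")
  if (any(r < 0) || any(r >= 1)) stop("priority r must be in [0, 1)")
  if (any(s < 1)) stop("stage target s must be >= 1")
  out <- ceiling(r * s / t)
  out[r == 0] <- 1
  as.integer(out)
}

#' Staffing- and efficiency-corrected cycle time
#'
#' The target cycle time `CT` assumes a fully staffed team working at 100%
#' FTE efficiency. With `C` chemists and `B` biologists assigned out of
#' targets `TC`/`TB`, and FTE efficiency `F`, the corrected time to the next
#' milestone decision is
#' \deqn{A = CT (TC + TB) / (F (C + B)),}
#' i.e. cycle time is linear in the reciprocal of effective staffing: a
#' half-staffed team takes twice as long, and two scientists at 50% efficiency
#' equal one at 100%. `dmpk_mult` carries the optional DMPK acceleration
#' factor `1 - dmpk_impact`.
#'
#' @param CT target cycle time, months.
#' @param TC,TB target chemists/biologists at the current stage.
#' @param F_eff FTE efficiency in (0, 1\].
#' @param C,B assigned chemists/biologists; `C + B >= 1`.
#' @param dmpk_mult timeline multiplier, 1 when unsupported.
#' @return Corrected cycle time `A` in months.
#' @export
#' @examples
#' corrected_cycle_time(12, 2, 2, 1, 1, 1)   # half-staffed: 24 months
corrected_cycle_time <- function(CT, TC, TB, F_eff, C, B, dmpk_mult = 1) {
  if (any(C + B < 1)) stop("a running project needs at least one scientist ",
                           "(zero-staffed projects must be on hold)")
  if (any(F_eff <= 0) || any(F_eff > 1)) stop("F_eff must be in (0, 1]")
  if (any(CT <= 0) || any(TC < 1) || any(TB < 1))
    stop("CT, TC and TB must be positive")
  CT * (TC + TB) / (F_eff * (C + B)) * dmpk_mult
}

#' Rescale a project clock after a staffing or support change
#'
#' When the corrected cycle time changes from `A_old` to `A_new` mid-stage,
#' the fraction of the stage already completed, `TE / A_old`, is preserved:
#' `TE <- A_new * TE / A_old` and `TD <- A_new * (1 - TE / A_old)`, so that
#' `TE + TD = A_new` still holds.
#'
#' @param project a list with numeric fields `A` (current corrected cycle
#'   time), `TE` (elapsed progress) and `TD` (time to decision).
#' @param A_new the new corrected cycle time.
#' @return The project list with `A`, `TE`, `TD` updated.
#' @export
#' @examples
#' rescale_clock(list(A = 24, TE = 6, TD = 18), 12)   # TE 3, TD 9
rescale_clock <- function(project, A_new) {
  if (is.na(project$A) || project$A <= 0) stop("project has no running clock")
  frac <- project$TE / project$A
  if (frac < 0 || frac > 1) stop("elapsed time TE must lie in [0, A]")
  project$TE <- A_new * frac
  project$TD <- A_new * (1 - frac)
  project$A <- A_new
  project
}

#' Classify a newly created hit-to-lead project
#'
#' Draws the project type from the portfolio mix: follow-on with probability
#' `pct_followon`, otherwise chemistry-driven with probability
#' `pct_chem_driven` and biology-driven with the remainder. Returns the type
#' together with its per-type hit-to-lead staffing targets.
#'
#' @param params a [pipeline_params()] object.
#' @return `list(type, chem_target, bio_target)` where `type` is one of
#'   `"chemistry_driven"`, `"biology_driven"`, `"follow_on"`.
#' @export
#' @examples
#' set.seed(1); classify_new_project(default_parameters())
classify_new_project <- function(params) {
  if (stats::runif(1) < params$pct_followon) {
    list(type = "follow_on",
         chem_target = as.integer(params$htl_chem_followon),
         bio_target = as.integer(params$htl_bio_followon))
  } else if (stats::runif(1) < params$pct_chem_driven) {
    list(type = "chemistry_driven",
         chem_target = as.integer(params$htl_chem_chemdriven),
         bio_target = as.integer(params$htl_bio_chemdriven))
  } else {
    list(type = "biology_driven",
         chem_target = as.integer(params$htl_chem_biodriven),
         bio_target = as.integer(params$htl_bio_biodriven))
  }
}

.type_codes <- c(chemistry_driven = 1L, biology_driven = 2L, follow_on = 3L)

# ---- internal state -------------------------------------------------------

new_state <- function(params,
                      total_years = params$warmup_years + params$collection_years,
                      log_events = FALSE) {
  v <- validate_params(params)
  if (length(v)) stop("invalid parameters:\n  ", paste(v, collapse = "\n  "))
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$F <- resolve_efficiency(params)
  st$month <- 0L
  st$total_years <- as.integer(total_years)
  st$free_c <- as.integer(params$n_chemists)
  st$free_b <- as.integer(params$n_biologists)
  st$accrual <- 0
  st$n <- 0L
  st$next_id <- 1L
  cap <- 64L
  st$alive <- logical(cap)
  st$stage <- integer(cap)   # 1 = hit_to_lead, 2 = lead_optimization
  st$type  <- integer(cap)
  st$r     <- numeric(cap)
  st$hi    <- logical(cap)
  st$C <- integer(cap); st$B <- integer(cap)
  st$TC <- integer(cap); st$TB <- integer(cap)
  st$capC <- integer(cap); st$capB <- integer(cap)
  st$A <- numeric(cap); st$TE <- numeric(cap); st$TD <- numeric(cap)
  st$entry <- integer(cap)
  st$hold <- logical(cap)
  st$dmpk <- logical(cap)
  st$id <- integer(cap)
  st$dmpk_used <- 0L
  st$pc_by_year <- numeric(total_years)
  st$lo_months <- numeric(total_years)
  st$term <- c(gate_htl = 0L, gate_lo = 0L, cutoff_htl = 0L, cutoff_lo = 0L,
               raided = 0L)
  st$log <- isTRUE(log_events)
  st$events <- list()
  st
}

log_event <- function(st, event, id = NA_integer_, detail = "") {
  if (st$log)
    st$events[[length(st$events) + 1L]] <-
      list(month = st$month, id = id, event = event, detail = detail)
  invisible(NULL)
}

# corrected cycle time for project slot i, from its current stage/staffing
eq1_A <- function(st, i) {
  p <- st$params
  CT <- if (st$stage[i] == 1L) p$ct_htl_to_lo else p$ct_lo_to_pd
  mult <- if (st$dmpk[i]) 1 - p$dmpk_impact else 1
  CT * (st$TC[i] + st$TB[i]) / (st$F * (st$C[i] + st$B[i])) * mult
}

# preserve the progress fraction TE/A when A changes (staffing, DMPK, resume)
rescale_slot <- function(st, i) {
  A_old <- st$A[i]
  A_new <- eq1_A(st, i)
  frac <- st$TE[i] / A_old
  st$TE[i] <- A_new * frac
  st$TD[i] <- A_new * (1 - frac)
  st$A[i] <- A_new
  invisible(NULL)
}

grow_state <- function(st) {
  n <- st$n
  keep <- which(st$alive[seq_len(n)])
  fields <- c("alive", "stage", "type", "r", "hi", "C", "B", "TC", "TB",
              "capC", "capB", "A", "TE", "TD", "entry", "hold", "dmpk", "id")
  if (length(keep) <= n * 0.75) {        # compact dead slots
    for (f in fields) {
      old <- st[[f]]
      new <- old
      new[seq_along(keep)] <- old[keep]
      length(new) <- length(old)
      st[[f]] <- new
    }
    st$n <- length(keep)
  } else {                               # double capacity
    for (f in fields) {
      old <- st[[f]]
      length(old) <- 2L * length(old)
      if (is.logical(st[[f]])) old[is.na(old)] <- FALSE
      st[[f]] <- old
    }
  }
  invisible(NULL)
}

add_project <- function(st, stage, type, r, C, B, TC, TB, capC, capB,
                        entry = st$month, hi = FALSE) {
  if (st$n >= length(st$alive)) grow_state(st)
  i <- st$n + 1L
  st$n <- i
  st$alive[i] <- TRUE
  st$stage[i] <- stage
  st$type[i] <- type
  st$r[i] <- r
  st$hi[i] <- hi
  st$C[i] <- as.integer(C); st$B[i] <- as.integer(B)
  st$TC[i] <- as.integer(TC); st$TB[i] <- as.integer(TB)
  st$capC[i] <- as.integer(capC); st$capB[i] <- as.integer(capB)
  st$entry[i] <- as.integer(entry)
  st$hold[i] <- FALSE
  st$dmpk[i] <- FALSE
  st$id[i] <- st$next_id
  st$next_id <- st$next_id + 1L
  if (C + B >= 1) {
    st$A[i] <- eq1_A(st, i)
    st$TD[i] <- st$A[i]
    st$TE[i] <- 0
  } else {
    st$A[i] <- NA_real_; st$TD[i] <- Inf; st$TE[i] <- 0
    st$hold[i] <- TRUE
  }
  i
}

terminate_slot <- function(st, i, cause) {
  st$free_c <- st$free_c + st$C[i]
  st$free_b <- st$free_b + st$B[i]
  st$C[i] <- 0L; st$B[i] <- 0L
  if (st$dmpk[i]) {
    st$dmpk_used <- st$dmpk_used - 1L
    st$dmpk[i] <- FALSE
  }
  st$alive[i] <- FALSE
  st$term[cause] <- st$term[cause] + 1L
  log_event(st, "terminated", st$id[i], cause)
  invisible(NULL)
}

# High-priority lead-optimization staffing: free (exploratory) scientists
# first, then drain hit-to-lead projects from the least supported upward.
# Drained projects are put on hold (or terminated under raid_mode =
# "terminate"); staff the target does not absorb returns to the free pool.
raid_staff <- function(st, i) {
  p <- st$params
  take <- min(st$TC[i] - st$C[i], st$free_c)
  st$C[i] <- st$C[i] + take; st$free_c <- st$free_c - take
  take <- min(st$TB[i] - st$B[i], st$free_b)
  st$B[i] <- st$B[i] + take; st$free_b <- st$free_b - take
  n <- st$n
  while (st$C[i] < st$TC[i] || st$B[i] < st$TB[i]) {
    cand <- which(st$alive[seq_len(n)] & st$stage[seq_len(n)] == 1L &
                    !st$hold[seq_len(n)] &
                    (st$C[seq_len(n)] + st$B[seq_len(n)]) > 0L)
    if (!length(cand)) break
    frac <- (st$C[cand] + st$B[cand]) / (st$TC[cand] + st$TB[cand])
    v <- cand[order(frac, st$entry[cand], st$id[cand])][1]
    vc <- st$C[v]; vb <- st$B[v]
    st$C[v] <- 0L; st$B[v] <- 0L
    if (identical(p$raid_mode, "terminate")) {
      st$alive[v] <- FALSE
      st$term["raided"] <- st$term["raided"] + 1L
      log_event(st, "terminated", st$id[v], "raided")
    } else {
      st$hold[v] <- TRUE
      log_event(st, "on_hold", st$id[v], "raided")
    }
    dc <- min(st$TC[i] - st$C[i], vc)
    st$C[i] <- st$C[i] + dc; st$free_c <- st$free_c + (vc - dc)
    db <- min(st$TB[i] - st$B[i], vb)
    st$B[i] <- st$B[i] + db; st$free_b <- st$free_b + (vb - db)
  }
  invisible(NULL)
}

gate_slot <- function(st, i) {
  p <- st$params
  if (st$stage[i] == 1L) {
    u <- stats::runif(1)
    if (u < p$p_lead_opt) {
      st$stage[i] <- 2L
      st$entry[i] <- st$month
      st$TC[i] <- as.integer(p$lo_chem_target)
      st$TB[i] <- as.integer(p$lo_bio_target)
      st$capC[i] <- st$TC[i]          # no priority ceiling at LO
      st$capB[i] <- st$TB[i]
      hi <- stats::runif(1) < p$pct_high_priority_lo
      st$hi[i] <- hi
      if (hi) raid_staff(st, i)
      st$TE[i] <- 0
      if (st$C[i] + st$B[i] >= 1L) {
        st$A[i] <- eq1_A(st, i)
        st$TD[i] <- st$A[i]
        st$hold[i] <- FALSE
      } else {
        st$A[i] <- NA_real_; st$TD[i] <- Inf
        st$hold[i] <- TRUE
      }
      log_event(st, "htl_to_lo", st$id[i],
                if (hi) "high_priority" else "standard")
    } else {
      terminate_slot(st, i, "gate_htl")
    }
  } else {
    u <- stats::runif(1)
    st$free_c <- st$free_c + st$C[i]
    st$free_b <- st$free_b + st$B[i]
    st$C[i] <- 0L; st$B[i] <- 0L
    if (st$dmpk[i]) {
      st$dmpk_used <- st$dmpk_used - 1L
      st$dmpk[i] <- FALSE
    }
    st$alive[i] <- FALSE
    if (u < p$p_preclinical) {
      yr <- (st$month - 1L) %/% 12L + 1L
      st$pc_by_year[yr] <- st$pc_by_year[yr] + 1
      log_event(st, "preclinical_candidate", st$id[i])
    } else {
      st$term["gate_lo"] <- st$term["gate_lo"] + 1L
      log_event(st, "terminated", st$id[i], "gate_lo")
    }
  }
  invisible(NULL)
}

allocate_dmpk_state <- function(st) {
  p <- st$params
  if (p$dmpk_capacity <= 0L || st$dmpk_used >= p$dmpk_capacity || st$n == 0L)
    return(invisible(NULL))
  n <- st$n
  cand <- which(st$alive[seq_len(n)] & st$stage[seq_len(n)] == 2L &
                  !st$dmpk[seq_len(n)] & !st$hold[seq_len(n)])
  if (!length(cand)) return(invisible(NULL))
  for (i in cand[order(st$entry[cand], st$id[cand])]) {
    if (st$dmpk_used >= p$dmpk_capacity) break
    st$dmpk[i] <- TRUE
    st$dmpk_used <- st$dmpk_used + 1L
    rescale_slot(st, i)
    log_event(st, "dmpk_support", st$id[i])
  }
  invisible(NULL)
}

# fill projects in `idx` to their per-discipline limits, most-understaffed
# (lowest staffed fraction) first; every placement rescales the clock
fill_tier <- function(st, idx, use_caps) {
  if (!length(idx) || (st$free_c <= 0L && st$free_b <= 0L))
    return(invisible(NULL))
  frac <- (st$C[idx] + st$B[idx]) / (st$TC[idx] + st$TB[idx])
  for (i in idx[order(frac, st$entry[idx], st$id[idx])]) {
    if (st$free_c <= 0L && st$free_b <= 0L) break
    maxC <- if (use_caps) min(st$TC[i], st$capC[i]) else st$TC[i]
    maxB <- if (use_caps) min(st$TB[i], st$capB[i]) else st$TB[i]
    dc <- min(maxC - st$C[i], st$free_c)
    db <- min(maxB - st$B[i], st$free_b)
    if (dc <= 0L && db <= 0L) next
    if (dc > 0L) { st$C[i] <- st$C[i] + dc; st$free_c <- st$free_c - dc }
    if (db > 0L) { st$B[i] <- st$B[i] + db; st$free_b <- st$free_b - db }
    if (st$hold[i]) {
      st$hold[i] <- FALSE
      if (is.na(st$A[i])) {              # never clocked (zero-staffed entry)
        st$A[i] <- eq1_A(st, i)
        st$TD[i] <- st$A[i]
        st$TE[i] <- 0
      } else {
        rescale_slot(st, i)
      }
      log_event(st, "resumed", st$id[i])
    } else {
      rescale_slot(st, i)
    }
  }
  invisible(NULL)
}

# Reassignment priority: (1) understaffed lead optimization, (2) hit-to-lead
# projects on hold, (3) understaffed active hit-to-lead, (4) whatever is left
# stays in the free pool and works on exploratory ideation.
reassign_state <- function(st) {
  if ((st$free_c <= 0L && st$free_b <= 0L) || st$n == 0L)
    return(invisible(NULL))
  n <- st$n
  al <- st$alive[seq_len(n)]
  s <- st$stage[seq_len(n)]
  fill_tier(st, which(al & s == 2L &
                        (st$C[seq_len(n)] < st$TC[seq_len(n)] |
                           st$B[seq_len(n)] < st$TB[seq_len(n)])),
            use_caps = FALSE)
  fill_tier(st, which(al & s == 1L & st$hold[seq_len(n)]), use_caps = TRUE)
  fill_tier(st, which(al & s == 1L & !st$hold[seq_len(n)] &
                        (st$C[seq_len(n)] < pmin(st$TC, st$capC)[seq_len(n)] |
                           st$B[seq_len(n)] < pmin(st$TB, st$capB)[seq_len(n)])),
            use_caps = TRUE)
  invisible(NULL)
}

# Free scientists accrue exploratory effort (F-weighted person-months); every
# 2 * exploratory_cycle_months of accrued effort funds one gate roll against
# p_hit_to_lead. A success becomes a hit-to-lead project with the default
# staffing of 1 chemist + 1 biologist, so spawning pauses while either
# discipline's free pool is empty (the accrual is retained).
spawn_attempts_state <- function(st) {
  p <- st$params
  st$accrual <- st$accrual + st$F * (st$free_c + st$free_b)
  need <- 2 * p$exploratory_cycle_months
  while (st$accrual >= need - 1e-9 && st$free_c >= 1L && st$free_b >= 1L) {
    st$accrual <- st$accrual - need
    r <- stats::runif(1)
    if (r < p$p_hit_to_lead) {
      cls <- classify_new_project(p)
      capC <- staff_cap(r, cls$chem_target, p$p_hit_to_lead)
      capB <- staff_cap(r, cls$bio_target, p$p_hit_to_lead)
      st$free_c <- st$free_c - 1L
      st$free_b <- st$free_b - 1L
      i <- add_project(st, stage = 1L, type = .type_codes[[cls$type]], r = r,
                       C = 1L, B = 1L,
                       TC = cls$chem_target, TB = cls$bio_target,
                       capC = capC, capB = capB)
      log_event(st, "spawned", st$id[i], cls$type)
    } else {
      log_event(st, "exploratory_failed")
    }
  }
  invisible(NULL)
}

check_conservation <- function(st) {
  n <- st$n
  if (n > 0L) {
    al <- st$alive[seq_len(n)]
    ac <- sum(st$C[seq_len(n)][al])
    ab <- sum(st$B[seq_len(n)][al])
  } else {
    ac <- 0L; ab <- 0L
  }
  if (ac + st$free_c != st$params$n_chemists ||
      ab + st$free_b != st$params$n_biologists)
    stop(sprintf(paste0("headcount conservation violated at month %d: ",
                        "chemists %d+%d/%d, biologists %d+%d/%d"),
                 st$month, ac, st$free_c, st$params$n_chemists,
                 ab, st$free_b, st$params$n_biologists))
  invisible(NULL)
}

# One simulated month. Order: advance clocks -> lifetime cutoffs -> gates ->
# DMPK allocation -> reassignment -> exploratory spawning -> bookkeeping.
step_state <- function(st) {
  p <- st$params
  st$month <- st$month + 1L
  m <- st$month
  n <- st$n
  if (n > 0L) {
    act <- which(st$alive[seq_len(n)] & !st$hold[seq_len(n)])
    st$TD[act] <- st$TD[act] - 1
    st$TE[act] <- st$TE[act] + 1
  }
  has_cut_h <- !is.na(p$htl_lifetime_cutoff)
  has_cut_l <- !is.na(p$lo_lifetime_cutoff)
  if ((has_cut_h || has_cut_l) && n > 0L) {
    for (i in which(st$alive[seq_len(n)])) {
      age <- m - st$entry[i]
      if (st$stage[i] == 1L) {
        if (has_cut_h && age > p$htl_lifetime_cutoff)
          terminate_slot(st, i, "cutoff_htl")
      } else if (has_cut_l && age > p$lo_lifetime_cutoff) {
        terminate_slot(st, i, "cutoff_lo")
      }
    }
  }
  n <- st$n
  if (n > 0L) {
    due <- which(st$alive[seq_len(n)] & !st$hold[seq_len(n)] &
                   st$TD[seq_len(n)] <= 1e-9)
    for (i in due) {
      # a raid earlier in this loop may have terminated or suspended i
      if (st$alive[i] && !st$hold[i]) gate_slot(st, i)
    }
  }
  allocate_dmpk_state(st)
  reassign_state(st)
  spawn_attempts_state(st)
  yr <- (m - 1L) %/% 12L + 1L
  n <- st$n
  if (n > 0L)
    st$lo_months[yr] <- st$lo_months[yr] +
      sum(st$alive[seq_len(n)] & st$stage[seq_len(n)] == 2L)
  check_conservation(st)
  invisible(st)
}

# ---- replicate- and run-level API ----------------------------------------

#' Derive a child seed from a base seed and index coordinates
#'
#' Deterministically folds integer coordinates (replicate number, sweep cell
#' indices, ...) into a base seed with a multiplicative congruential hash in
#' \[1, 2^31 - 2\], so replicates and sweep cells get stable, order-independent
#' random streams.
#'
#' @param base base seed (any integer).
#' @param ... integer coordinates.
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(42, 3, 7)
derive_seed <- function(base, ...) {
  h <- as.double(base) %% 2147483647
  if (h < 0) h <- h + 2147483647
  for (k in c(...)) {
    h <- (h * 48271 + (as.double(k) %% 65536) * 69621 + 1) %% 2147483647
  }
  as.integer(h) + 1L
}

#' Run one simulation replicate
#'
#' Simulates `warmup_years + collection_years` of months from an
#' all-exploratory start (every scientist free) and collects annual counts of
#' preclinical candidates and of concurrently active lead-optimization
#' projects over the post-warm-up collection window. The run is fully
#' reproducible from `seed`.
#'
#' @param params a [pipeline_params()] object.
#' @param seed integer seed for this replicate's random stream.
#' @param log_events record a structured event log (month, project id, event,
#'   detail); off by default.
#' @param keep_monthly keep a per-month diagnostic matrix (free and assigned
#'   headcounts, roster size, staffing-cap compliance).
#' @return A `pipeline_replicate` object: `annual_pc` (integer preclinical
#'   candidates per collection year), `annual_lo` (mean concurrently active
#'   lead-optimization projects per year), `mean_pc`, `terminations` by cause,
#'   `seed`, and optionally `events` / `monthly`.
#' @seealso [run_pipeline()] for replicate aggregates.
#' @export
#' @examples
#' r <- run_replicate(pipeline_params(collection_years = 5, warmup_years = 2), 1)
#' r$mean_pc
run_replicate <- function(params, seed, log_events = FALSE,
                          keep_monthly = FALSE) {
  set.seed(as.integer(seed))
  total_years <- params$warmup_years + params$collection_years
  st <- new_state(params, total_years, log_events = log_events)
  months <- total_years * 12L
  monthly <- if (keep_monthly)
    matrix(0, nrow = months, ncol = 7,
           dimnames = list(NULL, c("month", "free_c", "free_b", "assigned_c",
                                   "assigned_b", "n_active", "caps_ok")))
  for (m in seq_len(months)) {
    step_state(st)
    if (keep_monthly) {
      n <- st$n
      al <- if (n > 0L) st$alive[seq_len(n)] else logical(0)
      htl <- al & st$stage[seq_len(n)] == 1L
      caps_ok <- !n ||
        (all(st$C[seq_len(n)][htl] <= pmin(st$TC, st$capC)[seq_len(n)][htl]) &&
         all(st$B[seq_len(n)][htl] <= pmin(st$TB, st$capB)[seq_len(n)][htl]) &&
         all(st$C[seq_len(n)][al] <= st$TC[seq_len(n)][al]) &&
         all(st$B[seq_len(n)][al] <= st$TB[seq_len(n)][al]))
      monthly[m, ] <- c(st$month, st$free_c, st$free_b,
                        sum(st$C[seq_len(n)][al]), sum(st$B[seq_len(n)][al]),
                        sum(al), caps_ok)
    }
  }
  sel <- seq.int(params$warmup_years + 1L, total_years)
  res <- list(
    annual_pc = as.integer(st$pc_by_year[sel]),
    annual_lo = st$lo_months[sel] / 12,
    mean_pc = mean(st$pc_by_year[sel]),
    terminations = st$term,
    seed = as.integer(seed),
    collection_years = params$collection_years
  )
  if (log_events) res$events <- event_log_frame(st)
  if (keep_monthly) res$monthly <- monthly
  structure(res, class = "pipeline_replicate")
}

event_log_frame <- function(st) {
  if (!length(st$events))
    return(data.frame(month = integer(0), id = integer(0),
                      event = character(0), detail = character(0)))
  data.frame(
    month = vapply(st$events, function(e) as.integer(e$month), integer(1)),
    id = vapply(st$events, function(e) as.integer(e$id), integer(1)),
    event = vapply(st$events, function(e) e$event, character(1)),
    detail = vapply(st$events, function(e) e$detail, character(1))
  )
}

#' Run a replicated simulation
#'
#' Runs `n_replicates` independent replicates whose seeds are derived
#' deterministically from `base_seed` via [derive_seed()], and aggregates the
#' replicate means of annual preclinical-candidate output.
#'
#' @inheritParams run_replicate
#' @param base_seed integer base seed.
#' @param n_replicates number of replicates (default from `params`).
#' @return A `pipeline_run` object: `mean_pc` (grand mean preclinical
#'   candidates per year), `sd_pc` and `se_pc` across replicates,
#'   `replicate_means`, `mean_annual_lo`, pooled `terminations`, and the
#'   per-replicate results in `replicates`.
#' @export
#' @examples
#' run_pipeline(pipeline_params(collection_years = 5, warmup_years = 2),
#'              base_seed = 1, n_replicates = 3)$mean_pc
run_pipeline <- function(params, base_seed, n_replicates = params$n_replicates) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  reps <- lapply(seq_len(n_replicates), function(i)
    run_replicate(params, derive_seed(base_seed, i)))
  means <- vapply(reps, function(r) r$mean_pc, numeric(1))
  term <- Reduce(`+`, lapply(reps, function(r) r$terminations))
  structure(list(
    mean_pc = mean(means),
    sd_pc = if (n_replicates > 1) stats::sd(means) else NA_real_,
    se_pc = if (n_replicates > 1) stats::sd(means) / sqrt(n_replicates)
            else NA_real_,
    replicate_means = means,
    mean_annual_lo = mean(vapply(reps, function(r) mean(r$annual_lo),
                                 numeric(1))),
    terminations = term,
    base_seed = base_seed,
    n_replicates = n_replicates,
    replicates = reps
  ), class = "pipeline_run")
}

#' @export
print.pipeline_replicate <- function(x, ...) {
  cat("<pipeline_replicate>  seed", x$seed, "\n")
  cat(sprintf("  mean output: %.3f preclinical candidates/year over %d years\n",
              x$mean_pc, x$collection_years))
  cat("  annual counts:", paste(x$annual_pc, collapse = " "), "\n")
  invisible(x)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> ", x$n_replicates, "replicates, base seed",
      x$base_seed, "\n")
  cat(sprintf("  mean output: %.3f +/- %.3f (sd) preclinical candidates/year\n",
              x$mean_pc, x$sd_pc))
  cat(sprintf("  mean active lead-optimization projects: %.2f\n",
              x$mean_annual_lo))
  invisible(x)
}
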