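## Grid experiments over staffing and efficiency parameters. Every cell is an
## independent replicated run whose seed is derived from the base seed and the
## cell's axis values, so grids are reproducible, insensitive to evaluation
## order, and agree cell-for-cell with any subgrid or direct run.

new_sweep <- function(axis1_name, axis1, axis2_name, axis2, values, metric,
                      n_replicates, base_seed) {
  stopifnot(nrow(values) == length(axis1), ncol(values) == length(axis2))
  structure(list(
    axis1_name = axis1_name, axis1 = axis1,
    axis2_name = axis2_name, axis2 = axis2,
    values = values, metric = metric,
    n_replicates = n_replicates, base_seed = base_seed
  ), class = "pipeline_sweep")
}

#' @export
print.pipeline_sweep <- function(x, ...) {
  cat(sprintf("<pipeline_sweep> %s (%d x %d), %d replicates/cell, base seed %s\n",
              x$metric, length(x$axis1), length(x$axis2), x$n_replicates,
              format(x$base_seed)))
  cat(sprintf("  %s: %s\n", x$axis1_name, paste(x$axis1, collapse = " ")))
  cat(sprintf("  %s: %s\n", x$axis2_name, paste(x$axis2, collapse = " ")))
  m <- x$values
  dimnames(m) <- list(x$axis1, x$axis2)
  print(round(m, 3))
  invisible(x)
}

cell_metric <- function(run, metric) {
  switch(metric,
         pc = run$mean_pc,
         active_lo = run$mean_annual_lo,
         stop("unknown metric: ", metric))
}

#' Sweep the chemist x biologist staffing grid
#'
#' Runs a replicated simulation for every combination of working-group
#' chemist and biologist totals and records the mean output surface, either
#' preclinical candidates per year (`metric = "pc"`) or concurrently active
#' lead-optimization projects (`metric = "active_lo"`). Cell seeds are
#' `derive_seed(base_seed, chem_value, bio_value)`.
#'
#' @param params baseline [pipeline_params()]; the staffing fields are
#'   overridden cell by cell.
#' @param chem_values,bio_values positive integer axis values.
#' @param metric `"pc"` or `"active_lo"`.
#' @param base_seed integer base seed.
#' @param n_replicates replicates per cell (default from `params`).
#' @return A `pipeline_sweep` object with `values[i, j]` the mean for
#'   `chem_values[i]`, `bio_values[j]`.
#' @export
sweep_staff_grid <- function(params, chem_values, bio_values,
                             metric = c("pc", "active_lo"), base_seed,
                             n_replicates = params$n_replicates) {
  metric <- match.arg(metric)
  if (!length(chem_values) || !length(bio_values))
    stop("axis values must be non-empty")
  if (any(chem_values < 1) || any(bio_values < 1))
    stop("staffing axes must be positive integers")
  vals <- matrix(NA_real_, length(chem_values), length(bio_values))
  for (i in seq_along(chem_values)) {
    for (j in seq_along(bio_values)) {
      p <- params
      p$n_chemists <- as.integer(chem_values[i])
      p$n_biologists <- as.integer(bio_values[j])
      run <- run_pipeline(p, derive_seed(base_seed, chem_values[i],
                                         bio_values[j]), n_replicates)
      vals[i, j] <- cell_metric(run, metric)
    }
  }
  new_sweep("chemists", chem_values, "biologists", bio_values, vals, metric,
            n_replicates, base_seed)
}

#' Sweep the FTE-efficiency parameters M and N
#'
#' Runs the simulation over a grid of efficiency-curve anchors (`M`, group
#' size at 50% efficiency; `N`, at 75%). Cells violating `M >= N + 10` are
#' left `NA` (the curve would be implausibly steep).
#'
#' @inheritParams sweep_staff_grid
#' @param m_values,n_values positive integer axis values for `m50` and `n75`.
#' @return A `pipeline_sweep` with axis1 = M values, axis2 = N values; invalid
#'   cells are `NA`.
#' @export
sweep_efficiency <- function(params, m_values, n_values, base_seed,
                             n_replicates = params$n_replicates) {
  if (any(m_values < 1) || any(n_values < 1))
    stop("M and N axes must be positive")
  vals <- matrix(NA_real_, length(m_values), length(n_values))
  for (i in seq_along(m_values)) {
    for (j in seq_along(n_values)) {
      if (m_values[i] < n_values[j] + 10) next
      p <- params
      p$m50 <- as.integer(m_values[i])
      p$n75 <- as.integer(n_values[j])
      run <- run_pipeline(p, derive_seed(base_seed, m_values[i], n_values[j]),
                          n_replicates)
      vals[i, j] <- run$mean_pc
    }
  }
  new_sweep("M (50% efficiency)", m_values, "N (75% efficiency)", n_values,
            vals, "pc", n_replicates, base_seed)
}

#' Cellwise difference of two sweeps
#'
#' Subtracts sweep `b` from sweep `a` cell by cell, e.g. to map where adding
#' lifetime cutoffs changes productivity. The sweeps must share both axes.
#'
#' @param a,b `pipeline_sweep` objects on identical axes.
#' @return A `pipeline_sweep` of differences (`a - b`).
#' @export
difference_map <- function(a, b) {
  if (!inherits(a, "pipeline_sweep") || !inherits(b, "pipeline_sweep"))
    stop("difference_map() needs two pipeline_sweep objects")
  if (!identical(a$axis1, b$axis1) || !identical(a$axis2, b$axis2))
    stop("sweeps have mismatched axes")
  new_sweep(a$axis1_name, a$axis1, a$axis2_name, a$axis2,
            a$values - b$values, paste0("diff_", a$metric),
            a$n_replicates, a$base_seed)
}

#' Extract the equal-staffing diagonal of a square sweep
#'
#' For a square staffing grid with identical chemist and biologist axes,
#' returns the profile along the chemists-equal-biologists diagonal — the
#' leading edge of the productivity contour, suitable for [fit_biphasic()].
#'
#' @param sweep a square `pipeline_sweep` with `axis1 == axis2`.
#' @return `list(x = axis values, y = diagonal means)`.
#' @export
frontier_diagonal <- function(sweep) {
  if (!inherits(sweep, "pipeline_sweep")) stop("not a pipeline_sweep")
  if (length(sweep$axis1) != length(sweep$axis2) ||
      !isTRUE(all.equal(as.numeric(sweep$axis1), as.numeric(sweep$axis2))))
    stop("frontier_diagonal() needs a square grid with equal axes")
  list(x = sweep$axis1, y = diag(sweep$values))
}

#' Annual preclinical-candidate time series
#'
#' Runs a single replicate and returns its annual candidate counts, exposing
#' the irregular, clustered arrival pattern of candidate-selection events
#' (years of zero output interleaved with multi-candidate years).
#'
#' @inheritParams sweep_staff_grid
#' @param seed replicate seed.
#' @param years collection years (overrides `params$collection_years`).
#' @return Integer vector of preclinical candidates per year.
#' @export
annual_series <- function(params, seed, years = params$collection_years) {
  if (years < 1) stop("years must be >= 1")
  p <- params
  p$collection_years <- as.integer(years)
  run_replicate(p, seed)$annual_pc
}

#' Maximum output as a function of lead-optimization team size
#'
#' For each lead-optimization team size (split equally between chemists and
#' biologists), sweeps equal-staffed working groups over `group_range` totals
#' and records the maximum mean output, tracing how growing per-project team
#' requirements shrink the number of supportable projects.
#'
#' @inheritParams sweep_staff_grid
#' @param lo_team_sizes even positive integers (total scientists per
#'   lead-optimization team).
#' @param group_totals even working-group totals to scan (split equally).
#' @return `data.frame(team_size, max_pc, argmax_total)`.
#' @export
sweep_team_size <- function(params, lo_team_sizes, group_totals, base_seed,
                            n_replicates = params$n_replicates) {
  if (any(lo_team_sizes %% 2 != 0) || any(lo_team_sizes < 2))
    stop("lo_team_sizes must be even (split equally between disciplines)")
  if (any(group_totals %% 2 != 0)) stop("group_totals must be even")
  out <- data.frame(team_size = lo_team_sizes, max_pc = NA_real_,
                    argmax_total = NA_integer_)
  for (k in seq_along(lo_team_sizes)) {
    ts <- lo_team_sizes[k]
    best <- -Inf; arg <- NA_integer_
    for (g in seq_along(group_totals)) {
      p <- params
      p$lo_chem_target <- as.integer(ts / 2)
      p$lo_bio_target <- as.integer(ts / 2)
      p$n_chemists <- as.integer(group_totals[g] / 2)
      p$n_biologists <- as.integer(group_totals[g] / 2)
      run <- run_pipeline(p, derive_seed(base_seed, ts, group_totals[g]),
                          n_replicates)
      if (run$mean_pc > best) { best <- run$mean_pc; arg <- group_totals[g] }
    }
    out$max_pc[k] <- best
    out$argmax_total[k] <- arg
  }
  out
}

#' Sweep the project-portfolio mix
#'
#' Grid of mean output over the follow-on fraction (0 to 0.5) and the
#' chemistry-driven fraction of the remainder (0 to 1), holding staffing and
#' all other parameters fixed.
#'
#' @inheritParams sweep_staff_grid
#' @param followon_values fractions in \[0, 0.5\].
#' @param chemdriven_values fractions in \[0, 1\].
#' @return A `pipeline_sweep` with axis1 = follow-on fractions, axis2 =
#'   chemistry-driven fractions.
#' @export
sweep_project_mix <- function(params, followon_values, chemdriven_values,
                              base_seed, n_replicates = params$n_replicates) {
  if (any(followon_values < 0) || any(followon_values > 0.5))
    stop("followon_values must lie in [0, 0.5]")
  if (any(chemdriven_values < 0) || any(chemdriven_values > 1))
    stop("chemdriven_values must lie in [0, 1]")
  vals <- matrix(NA_real_, length(followon_values), length(chemdriven_values))
  for (i in seq_along(followon_values)) {
    for (j in seq_along(chemdriven_values)) {
      p <- params
      p$pct_followon <- followon_values[i]
      p$pct_chem_driven <- chemdriven_values[j]
      run <- run_pipeline(p, derive_seed(base_seed,
                                         round(1000 * followon_values[i]),
                                         round(1000 * chemdriven_values[j])),
                          n_replicates)
      vals[i, j] <- run$mean_pc
    }
  }
  new_sweep("pct_followon", followon_values, "pct_chem_driven",
            chemdriven_values, vals, "pc", n_replicates, base_seed)
}
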