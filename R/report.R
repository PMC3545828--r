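## Output files, manifests and the programmatic backends of the command-line
## driver (inst/cli/ddpipesim.R). The legacy single-column output format is
## row-major: outer axis = chemists ascending, inner axis = biologists
## ascending.

#' Flatten a sweep to the legacy single-column file
#'
#' Writes one mean-output value per line, row-major (axis 1 outer and
#' ascending, axis 2 inner and ascending), the historical plain-text form that
#' downstream plotting tools reshape into a matrix. `NA` cells (e.g. invalid
#' M/N combinations) are written as `NA`.
#'
#' @param sweep a `pipeline_sweep`.
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [to_matrix()] for the reshape, [write_sweep_csv()] for the labeled
#'   matrix.
#' @export
write_column_file <- function(sweep, path) {
  if (!inherits(sweep, "pipeline_sweep")) stop("not a pipeline_sweep")
  vals <- as.vector(t(sweep$values))   # row-major: axis1 outer, axis2 inner
  writeLines(vapply(vals, function(v)
    if (is.na(v)) "NA" else format(v, digits = 15, scientific = FALSE),
    character(1)), path)
  invisible(path)
}

#' Reshape a single-column output file into a matrix file
#'
#' Reads a one-value-per-line column file and rewrites it as `n_rows` lines of
#' `n_cols` tab-separated values, row-major, preserving each value's text
#' representation exactly. Errors when the line count does not equal
#' `n_rows * n_cols`.
#'
#' @param column_path path to the single-column file.
#' @param n_rows,n_cols target matrix shape.
#' @param matrix_path output path.
#' @return `matrix_path`, invisibly.
#' @export
to_matrix <- function(column_path, n_rows, n_cols, matrix_path) {
  lines <- readLines(column_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != n_rows * n_cols)
    stop(sprintf("column file has %d values; cannot reshape to %d x %d",
                 length(lines), n_rows, n_cols))
  rows <- vapply(seq_len(n_rows), function(i)
    paste(lines[((i - 1) * n_cols + 1):(i * n_cols)], collapse = "\t"),
    character(1))
  writeLines(rows, matrix_path)
  invisible(matrix_path)
}

#' Write a sweep as a labeled CSV matrix
#'
#' Axis-1 values become the first column, axis-2 values the header.
#'
#' @inheritParams write_column_file
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  if (!inherits(sweep, "pipeline_sweep")) stop("not a pipeline_sweep")
  m <- sweep$values
  df <- data.frame(sweep$axis1, m, check.names = FALSE)
  names(df) <- c(paste0(sweep$axis1_name, "\\", sweep$axis2_name),
                 as.character(sweep$axis2))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(out_dir, command, control_path, seed, replicates,
                           extra = list()) {
  manifest <- c(list(
    command = command,
    control_file = normalizePath(control_path, mustWork = FALSE),
    base_seed = seed,
    replicates = replicates,
    tool = "ddpipesim",
    version = as.character(utils::packageVersion("ddpipesim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Run a simulation from a control file and write result files
#'
#' Backend of the `simulate` command of the bundled command-line driver:
#' reads and validates the control file, runs the replicated simulation, and
#' writes `summary.txt` (mean, sd, replicate count), `replicates.csv`
#' (per-replicate means and termination tallies), `annual_series.csv`
#' (per-replicate annual candidate counts) and `manifest.json` into `out_dir`.
#'
#' @param control_path path to a tab-delimited control file.
#' @param seed base seed.
#' @param out_dir output directory (created if needed).
#' @param replicates replicate count; `NULL` uses the control file's value.
#' @return The `pipeline_run`, invisibly.
#' @export
cli_simulate <- function(control_path, seed, out_dir, replicates = NULL) {
  params <- read_control_file(control_path)
  if (!is.null(replicates)) params$n_replicates <- as.integer(replicates)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run <- run_pipeline(params, base_seed = seed)
  writeLines(c(
    sprintf("mean_pc_per_year\t%.6f", run$mean_pc),
    sprintf("sd_pc_per_year\t%.6f", run$sd_pc),
    sprintf("se_pc_per_year\t%.6f", run$se_pc),
    sprintf("mean_active_lo\t%.6f", run$mean_annual_lo),
    sprintf("replicates\t%d", run$n_replicates),
    sprintf("base_seed\t%d", seed)
  ), file.path(out_dir, "summary.txt"))
  reps <- run$replicates
  term <- t(vapply(reps, function(r) r$terminations,
                   numeric(length(reps[[1]]$terminations))))
  utils::write.csv(data.frame(
    replicate = seq_along(reps),
    seed = vapply(reps, function(r) r$seed, integer(1)),
    mean_pc = vapply(reps, function(r) r$mean_pc, numeric(1)),
    term), file.path(out_dir, "replicates.csv"), row.names = FALSE)
  ann <- t(vapply(reps, function(r) as.numeric(r$annual_pc),
                  numeric(length(reps[[1]]$annual_pc))))
  colnames(ann) <- paste0("year", seq_len(ncol(ann)))
  utils::write.csv(data.frame(replicate = seq_along(reps), ann),
                   file.path(out_dir, "annual_series.csv"), row.names = FALSE)
  write_manifest(out_dir, "simulate", control_path, seed, run$n_replicates)
  invisible(run)
}

#' Run a staffing sweep from a control file and write result files
#'
#' Backend of the `sweep` command: runs [sweep_staff_grid()] over the given
#' axes and writes the legacy single-column file (`sweep_column.txt`), the
#' labeled matrix (`sweep_matrix.csv`) and `manifest.json`.
#'
#' @inheritParams cli_simulate
#' @param chem_values,bio_values integer axis values.
#' @param metric `"pc"` or `"active_lo"`.
#' @return The `pipeline_sweep`, invisibly.
#' @export
cli_sweep <- function(control_path, chem_values, bio_values, seed, out_dir,
                      metric = "pc", replicates = NULL) {
  params <- read_control_file(control_path)
  if (!is.null(replicates)) params$n_replicates <- as.integer(replicates)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sweep <- sweep_staff_grid(params, chem_values, bio_values, metric = metric,
                            base_seed = seed)
  write_column_file(sweep, file.path(out_dir, "sweep_column.txt"))
  write_sweep_csv(sweep, file.path(out_dir, "sweep_matrix.csv"))
  write_manifest(out_dir, "sweep", control_path, seed, params$n_replicates,
                 extra = list(metric = metric,
                              chemists = paste(chem_values, collapse = ","),
                              biologists = paste(bio_values, collapse = ",")))
  invisible(sweep)
}

#' Parse an axis specification string
#'
#' Accepts `from:to:by` (e.g. `"2:40:2"`), `from:to`, or a comma list
#' (`"6,12,18"`), as used by the command-line driver.
#'
#' @param spec specification string.
#' @return Integer vector.
#' @export
#' @examples
#' parse_axis_spec("3:30:3")
parse_axis_spec <- function(spec) {
  spec <- trimws(spec)
  if (grepl(",", spec)) {
    out <- suppressWarnings(as.numeric(strsplit(spec, ",")[[1]]))
  } else if (grepl(":", spec)) {
    parts <- suppressWarnings(as.numeric(strsplit(spec, ":")[[1]]))
    if (length(parts) == 2) parts <- c(parts, 1)
    if (length(parts) != 3 || anyNA(parts))
      stop("malformed axis spec: ", sQuote(spec))
    out <- seq(parts[1], parts[2], by = parts[3])
  } else {
    out <- suppressWarnings(as.numeric(spec))
  }
  if (anyNA(out) || !length(out)) stop("malformed axis spec: ", sQuote(spec))
  if (any(out != floor(out))) stop("axis values must be integers: ", sQuote(spec))
  as.integer(out)
}
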