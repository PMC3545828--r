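#' Simulation parameter set
#'
#' A `pipeline_params` object collects every user-controlled value of the
#' pipeline simulator: milestone transition probabilities, the portfolio mix
#' (follow-on and chemistry- vs biology-driven projects), per-stage staffing
#' targets, DMPK support, target cycle times, the FTE-efficiency group sizes
#' (M at 50%, N at 75%), working-group totals, run control, and the engine
#' extensions (lifetime cutoffs, warm-up period, exploratory cycle time).
#'
#' Field-by-field:
#' \describe{
#'   \item{p_hit_to_lead, p_lead_opt, p_preclinical}{Go/no-go success
#'     probabilities for the exploratory -> hit-to-lead, hit-to-lead -> lead
#'     optimization, and lead optimization -> preclinical development
#'     milestones, each in \[0, 1\].}
#'   \item{pct_followon}{Fraction of new hit-to-lead projects that are
#'     follow-on (back-up) series sharing a biological target with an ongoing
#'     program; range \[0, 0.5\].}
#'   \item{pct_chem_driven}{Fraction of the non-follow-on projects that are
#'     chemistry-driven (the balance are biology/HTS-driven); range \[0, 1\].}
#'   \item{pct_high_priority_lo}{Fraction of lead-optimization projects
#'     designated high priority at stage entry; range \[0, 1\].}
#'   \item{htl_chem_chemdriven, htl_bio_chemdriven, htl_chem_biodriven,
#'     htl_bio_biodriven, htl_chem_followon, htl_bio_followon}{Target numbers
#'     of chemists/biologists per hit-to-lead team, by project type
#'     (positive integers).}
#'   \item{lo_chem_target, lo_bio_target}{Target chemists/biologists per
#'     lead-optimization team (positive integers).}
#'   \item{dmpk_capacity}{Number of lead-optimization projects that can hold
#'     DMPK support simultaneously (integer >= 0).}
#'   \item{dmpk_impact}{Fractional timeline shortening for a DMPK-supported
#'     project, in \[0, 1\].}
#'   \item{ct_htl_to_lo, ct_lo_to_pd}{Target cycle times in months for a fully
#'     staffed team at 100% FTE efficiency to reach the next milestone
#'     (positive integers).}
#'   \item{n75, m50}{Working-group sizes at which FTE efficiency is 75% and
#'     50%; `m50 > n75` (positive integers).}
#'   \item{efficiency_override}{Optional static FTE efficiency in (0, 1\]
#'     bypassing the logistic; `NA` to use the group-size curve.}
#'   \item{n_chemists, n_biologists}{Total scientists in the working group.}
#'   \item{collection_years, warmup_years, n_replicates}{Run control: years of
#'     data collection after the discarded warm-up transient, and replicate
#'     count.}
#'   \item{htl_lifetime_cutoff, lo_lifetime_cutoff}{Optional maximum wall-clock
#'     stage ages in months (`NA` = no cutoff); projects older than the cutoff
#'     are terminated and their scientists reassigned.}
#'   \item{exploratory_cycle_months}{Months of two-scientist effort that one
#'     exploratory (ideation/screening) attempt consumes before its milestone
#'     roll; the engine's only free parameter (see the methods vignette for
#'     its calibration).}
#'   \item{raid_mode}{What happens to a hit-to-lead project whose scientists
#'     are taken to staff a high-priority lead-optimization campaign:
#'     `"terminate"` (default; the drained project is killed) or `"hold"`
#'     (suspended with its progress frozen and re-staffed when scientists
#'     free up, though it keeps aging toward any lifetime cutoff).}
#' }
#'
#' @param ... named fields overriding the defaults of [default_parameters()].
#' @return A validated object of class `pipeline_params` (a named list).
#' @seealso [default_parameters()], [read_control_file()], [validate_params()]
#' @export
#' @examples
#' p <- pipeline_params(n_chemists = 10, n_biologists = 10)
#' p$p_hit_to_lead
pipeline_params <- function(...) {
  p <- default_parameters()
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all arguments to pipeline_params() must be named")
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  p <- structure(p, class = "pipeline_params")
  v <- validate_params(p)
  if (length(v)) stop("invalid parameters:\n  ", paste(v, collapse = "\n  "))
  p
}

#' Default simulation parameters
#'
#' Returns the package's reference configuration: literature-reported milestone
#' transition probabilities (80/75/85%), a portfolio of 25% follow-on projects
#' with an even chemistry/biology split of the remainder, all-standard-priority
#' lead optimization, the per-type staffing targets and 18/24-month cycle
#' times of the worked example in the package documentation, and FTE
#' efficiency reaching 75% at a group of 20 and 50% at 40. Engine extensions
#' default to: no lifetime cutoffs, 18 chemists + 18 biologists, 10 warm-up
#' years, 25 collection years, 50 replicates, and an exploratory cycle of 6
#' months (see the methods vignette for the calibration behind this value).
#'
#' @return A `pipeline_params` object.
#' @export
#' @examples
#' default_parameters()$p_preclinical
default_parameters <- function() {
  structure(list(
    p_hit_to_lead        = 0.80,
    p_lead_opt           = 0.75,
    p_preclinical        = 0.85,
    pct_followon         = 0.25,
    pct_chem_driven      = 0.5,
    pct_high_priority_lo = 0,
    htl_chem_chemdriven  = 2L,
    htl_bio_chemdriven   = 3L,
    htl_chem_biodriven   = 1L,
    htl_bio_biodriven    = 3L,
    htl_chem_followon    = 2L,
    htl_bio_followon     = 1L,
    lo_chem_target       = 4L,
    lo_bio_target        = 4L,
    dmpk_capacity        = 0L,
    dmpk_impact          = 0.1,
    ct_htl_to_lo         = 18L,
    ct_lo_to_pd          = 24L,
    n75                  = 20L,
    m50                  = 40L,
    efficiency_override  = NA_real_,
    n_chemists           = 18L,
    n_biologists         = 18L,
    collection_years     = 25L,
    warmup_years         = 10L,
    n_replicates         = 50L,
    htl_lifetime_cutoff  = NA_real_,
    lo_lifetime_cutoff   = NA_real_,
    exploratory_cycle_months = 6,
    raid_mode            = "terminate"
  ), class = "pipeline_params")
}

# Fields that must be whole numbers (silently rounding a control file would
# hide configuration errors, so fractional values are rejected).
.int_fields <- c(
  "htl_chem_chemdriven", "htl_bio_chemdriven", "htl_chem_biodriven",
  "htl_bio_biodriven", "htl_chem_followon", "htl_bio_followon",
  "lo_chem_target", "lo_bio_target", "dmpk_capacity",
  "ct_htl_to_lo", "ct_lo_to_pd", "n75", "m50",
  "n_chemists", "n_biologists",
  "collection_years", "warmup_years", "n_replicates"
)

#' Validate a parameter set
#'
#' Checks every invariant of a [pipeline_params()] object and reports all
#' violations, naming the field, the offending value, and the permitted range.
#' An empty character vector means the parameter set is valid.
#'
#' @param params a `pipeline_params` object (or plain named list with the same
#'   fields).
#' @return Character vector of violation messages; `length(0)` if valid.
#' @export
#' @examples
#' validate_params(default_parameters())          # character(0)
#' p <- default_parameters(); p$m50 <- p$n75
#' validate_params(p)
validate_params <- function(params) {
  v <- character(0)
  bad <- function(msg) v <<- c(v, msg)
  num1 <- function(field) {
    x <- params[[field]]
    if (is.null(x) || length(x) != 1 || !is.numeric(x)) {
      bad(sprintf("%s: must be a single numeric value", field))
      return(NA_real_)
    }
    as.numeric(x)
  }
  in_range <- function(field, lo, hi, label) {
    x <- num1(field)
    if (!is.na(x) && (x < lo || x > hi))
      bad(sprintf("%s: value %g outside permitted range %s", field, x, label))
  }
  in_range("p_hit_to_lead", 0, 1, "[0, 1]")
  in_range("p_lead_opt", 0, 1, "[0, 1]")
  in_range("p_preclinical", 0, 1, "[0, 1]")
  in_range("pct_followon", 0, 0.5, "[0, 0.5]")
  in_range("pct_chem_driven", 0, 1, "[0, 1]")
  in_range("pct_high_priority_lo", 0, 1, "[0, 1]")
  in_range("dmpk_impact", 0, 1, "[0, 1]")

  for (f in .int_fields) {
    x <- num1(f)
    if (is.na(x)) next
    if (x != floor(x))
      bad(sprintf("%s: value %g is not an integer", f, x))
  }
  pos_int <- c("htl_chem_chemdriven", "htl_bio_chemdriven",
               "htl_chem_biodriven", "htl_bio_biodriven",
               "htl_chem_followon", "htl_bio_followon",
               "lo_chem_target", "lo_bio_target",
               "ct_htl_to_lo", "ct_lo_to_pd", "n75", "m50",
               "collection_years", "n_replicates")
  for (f in pos_int) {
    x <- suppressWarnings(as.numeric(params[[f]]))
    if (length(x) == 1 && !is.na(x) && x < 1)
      bad(sprintf("%s: value %g must be a positive integer (>= 1)", f, x))
  }
  for (f in c("dmpk_capacity", "n_chemists", "n_biologists", "warmup_years")) {
    x <- suppressWarnings(as.numeric(params[[f]]))
    if (length(x) == 1 && !is.na(x) && x < 0)
      bad(sprintf("%s: value %g must be non-negative", f, x))
  }

  m <- suppressWarnings(as.numeric(params$m50))
  n <- suppressWarnings(as.numeric(params$n75))
  if (length(m) == 1 && length(n) == 1 && !is.na(m) && !is.na(n) && m <= n)
    bad(sprintf("m50: value %g must exceed n75 (%g)", m, n))

  ov <- params$efficiency_override
  if (!is.null(ov) && length(ov) == 1 && !is.na(ov)) {
    if (!is.numeric(ov) || ov <= 0 || ov > 1)
      bad(sprintf("efficiency_override: value %s outside permitted range (0, 1]",
                  format(ov)))
  }
  for (f in c("htl_lifetime_cutoff", "lo_lifetime_cutoff")) {
    x <- params[[f]]
    if (!is.null(x) && length(x) == 1 && !is.na(x) && (!is.numeric(x) || x <= 0))
      bad(sprintf("%s: value %s must be a positive number of months or NA", f,
                  format(x)))
  }
  ecm <- params$exploratory_cycle_months
  if (is.null(ecm) || length(ecm) != 1 || is.na(ecm) || !is.numeric(ecm) || ecm <= 0)
    bad("exploratory_cycle_months: must be a positive number of months")
  if (!identical(params$raid_mode, "hold") && !identical(params$raid_mode, "terminate"))
    bad("raid_mode: must be \"hold\" or \"terminate\"")
  v
}

# ---- control-file dialect -------------------------------------------------

# Canonical label for each field, written by write_control_file() and
# recognised (case-insensitively, with whitespace collapsed) by
# read_control_file(). The first 20 labels are required in every control
# file; the remainder are optional engine extensions with defaults, so a
# minimal 20-line file stays valid.
.control_labels <- c(
  p_hit_to_lead        = "Probability of achieving Hit to Lead milestone",
  p_lead_opt           = "Probability of achieving Lead Optimization milestone",
  p_preclinical        = "Probability of achieving Preclinical Development milestone",
  pct_followon         = "Percentage of follow-on Hit to Lead projects",
  pct_chem_driven      = "Percentage of chemistry-driven Hit to Lead projects",
  pct_high_priority_lo = "Percentage of prioritized Lead Optimization projects",
  htl_chem_chemdriven  = "Target no. Hit to Lead CHEMISTS (chemistry-driven) per team",
  htl_bio_chemdriven   = "Target no. Hit to Lead BIOLOGISTS (chemistry-driven) per team",
  htl_chem_biodriven   = "Target no. Hit to Lead CHEMISTS (biology-driven) per team",
  htl_bio_biodriven    = "Target no. Hit to Lead BIOLOGISTS (biology-driven) per team",
  htl_chem_followon    = "Target no. Hit to Lead CHEMISTS (follow-on) per team",
  htl_bio_followon     = "Target no. Hit to Lead BIOLOGISTS (follow-on) per team",
  lo_chem_target       = "Target no. Lead Optimization CHEMISTS per team",
  lo_bio_target        = "Target no. Lead Optimization BIOLOGISTS per team",
  dmpk_capacity        = "No. simultaneous Lead Optimization projects supported by DMPK",
  dmpk_impact          = "Percent impact on timeline by DMPK support",
  ct_htl_to_lo         = "Target cycle time (months) to achieve Lead Optimization",
  ct_lo_to_pd          = "Target cycle time (months) to achieve Preclinical Development",
  n75                  = "Group size at 75% FTE efficiency",
  m50                  = "Group size at 50% FTE efficiency",
  n_chemists           = "Total no. CHEMISTS in working group",
  n_biologists         = "Total no. BIOLOGISTS in working group",
  collection_years     = "Data collection period (years)",
  warmup_years         = "Warm-up period excluded from collection (years)",
  n_replicates         = "Number of replicate runs",
  efficiency_override  = "FTE efficiency override (blank or NA = use curve)",
  htl_lifetime_cutoff  = "Hit to Lead project lifetime cutoff (months)",
  lo_lifetime_cutoff   = "Lead Optimization project lifetime cutoff (months)",
  exploratory_cycle_months = "Exploratory cycle time (months)",
  raid_mode            = "High-priority staffing of on-going projects (hold or terminate)"
)
.required_fields <- names(.control_labels)[1:20]

.normalize_label <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' Read a tab-delimited control file
#'
#' Parses a simulation control file with one `label<TAB>value` pair per line,
#' in any order. Labels are matched case-insensitively with runs of
#' whitespace collapsed; blank lines and lines starting with `#` are skipped.
#' Unknown labels produce a warning; a missing required label or an invalid
#' value is an error. Optional engine-extension labels (working-group totals,
#' run control, cutoffs, exploratory cycle, efficiency override) fall back to
#' [default_parameters()] so a minimal 20-line file remains valid.
#'
#' @param path path to the control file.
#' @return A validated `pipeline_params` object.
#' @seealso [write_control_file()], [default_parameters()]
#' @export
#' @examples
#' path <- system.file("extdata", "table1_control.txt", package = "ddpipesim")
#' read_control_file(path)$ct_htl_to_lo
read_control_file <- function(path) {
  if (!file.exists(path)) stop("control file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^[[:space:]]*#", lines)]
  lookup <- stats::setNames(names(.control_labels), .normalize_label(.control_labels))
  p <- unclass(default_parameters())
  seen <- character(0)
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2)
      stop("unparseable control line (expected label<TAB>value): ", sQuote(ln))
    label <- .normalize_label(parts[1])
    value <- trimws(paste(parts[-1], collapse = "\t"))
    idx <- match(label, names(lookup))
    if (is.na(idx)) {
      warning("ignoring unknown control-file label: ", sQuote(parts[1]))
      next
    }
    field <- lookup[[idx]]
    seen <- c(seen, field)
    if (field == "raid_mode") {
      p[[field]] <- tolower(value)
    } else if (field %in% c("efficiency_override", "htl_lifetime_cutoff",
                            "lo_lifetime_cutoff") &&
               (value == "" || toupper(value) == "NA")) {
      p[[field]] <- NA_real_
    } else {
      num <- suppressWarnings(as.numeric(value))
      if (is.na(num))
        stop("unparseable value ", sQuote(value), " for field ", sQuote(field))
      if (field %in% .int_fields) {
        if (num != floor(num))
          stop(sprintf("field %s requires an integer value, got %s",
                       sQuote(field), value))
        p[[field]] <- as.integer(num)
      } else {
        p[[field]] <- num
      }
    }
  }
  missing <- setdiff(.required_fields, seen)
  if (length(missing))
    stop("control file is missing required field(s): ",
         paste(sprintf("%s (%s)", missing, .control_labels[missing]),
               collapse = "; "))
  p <- structure(p, class = "pipeline_params")
  v <- validate_params(p)
  if (length(v))
    stop("control file failed validation:\n  ", paste(v, collapse = "\n  "))
  p
}

#' Write a tab-delimited control file
#'
#' Serialises a parameter set as `label<TAB>value` lines using the canonical
#' labels; [read_control_file()] on the result reproduces the input exactly.
#'
#' @param params a `pipeline_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
#' @examples
#' f <- tempfile()
#' write_control_file(default_parameters(), f)
#' identical(read_control_file(f), default_parameters())
write_control_file <- function(params, path) {
  v <- validate_params(params)
  if (length(v)) stop("refusing to write invalid parameters:\n  ",
                      paste(v, collapse = "\n  "))
  fmt <- function(field) {
    x <- params[[field]]
    if (field == "raid_mode") return(x)
    if (length(x) == 1 && is.na(x)) return("NA")
    format(x, scientific = FALSE, trim = TRUE)
  }
  lines <- vapply(names(.control_labels),
                  function(f) paste(.control_labels[[f]], fmt(f), sep = "\t"),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.pipeline_params <- function(x, ...) {
  cat("<pipeline_params>\n")
  cat(sprintf("  gates: HTL %.2f | LO %.2f | PD %.2f\n",
              x$p_hit_to_lead, x$p_lead_opt, x$p_preclinical))
  cat(sprintf("  portfolio: %.0f%% follow-on, %.0f%% chemistry-driven, %.0f%% high-priority LO\n",
              100 * x$pct_followon, 100 * x$pct_chem_driven,
              100 * x$pct_high_priority_lo))
  cat(sprintf("  group: %d chemists + %d biologists; efficiency %s\n",
              x$n_chemists, x$n_biologists,
              if (is.na(x$efficiency_override))
                sprintf("logistic (M=%d, N=%d)", x$m50, x$n75)
              else sprintf("override %.2f", x$efficiency_override)))
  cat(sprintf("  cycle times: HTL->LO %d mo, LO->PD %d mo; cutoffs %s/%s mo\n",
              x$ct_htl_to_lo, x$ct_lo_to_pd,
              ifelse(is.na(x$htl_lifetime_cutoff), "-", x$htl_lifetime_cutoff),
              ifelse(is.na(x$lo_lifetime_cutoff), "-", x$lo_lifetime_cutoff)))
  cat(sprintf("  run: %d warm-up + %d collection years, %d replicates\n",
              x$warmup_years, x$collection_years, x$n_replicates))
  invisible(x)
}
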