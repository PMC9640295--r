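#' Reading validity rules
#'
#' Screening bounds applied to individual cuff inflations before any session
#' mean is formed, together with the minimum number of valid readings a
#' session needs per period to be analysable. The trials' own editing
#' criteria are not published, so these defaults are an explicit convention
#' of this package and every bound is configurable.
#'
#' @param sbp_bounds numeric length-2, plausible systolic range in mmHg.
#' @param dbp_bounds numeric length-2, plausible diastolic range in mmHg.
#' @param hr_bounds numeric length-2, plausible heart-rate range in bpm.
#' @param require_sbp_gt_dbp drop readings whose systolic value does not
#'   exceed the diastolic value.
#' @param min_day,min_night minimum counts of valid readings for the daytime
#'   and night-time periods; sessions below either are flagged and excluded
#'   from downstream analyses (but kept in the session table).
#' @return an object of class `validity_rules`.
#' @export
validity_rules <- function(sbp_bounds = c(60, 260),
                           dbp_bounds = c(40, 150),
                           hr_bounds = c(30, 200),
                           require_sbp_gt_dbp = TRUE,
                           min_day = 14L,
                           min_night = 7L) {
  for (b in list(sbp_bounds, dbp_bounds, hr_bounds)) {
    stopifnot(length(b) == 2L, b[1] < b[2])
  }
  stopifnot(min_day >= 1L, min_night >= 1L)
  structure(list(
    sbp_bounds = sbp_bounds, dbp_bounds = dbp_bounds, hr_bounds = hr_bounds,
    require_sbp_gt_dbp = isTRUE(require_sbp_gt_dbp),
    min_day = as.integer(min_day), min_night = as.integer(min_night)
  ), class = "validity_rules")
}

#' Analysis configuration
#'
#' Bundles the knobs shared across the pipeline: reading validity rules,
#' confidence-interval coverage and method for the within-individual CoV,
#' the Bonferroni family used by the arm-eligibility screen, and the
#' (mean, parameter) pairs illustrated as 95% reading ranges in reports.
#'
#' @param rules a [validity_rules()] object.
#' @param coverage confidence-interval coverage, in (0, 1).
#' @param ci_method `"delta"` for the normal-theory interval on the
#'   log-scale SD, or `"chisq"` for the chi-square interval.
#' @param bonferroni `"pairwise"` multiplies the first-vs-last post hoc p by
#'   the number of pairwise timepoint comparisons t(t-1)/2; `"single"` uses
#'   multiplier 1.
#' @param ht_threshold baseline daytime systolic mean (mmHg) at or above
#'   which an individual is classed hypertensive.
#' @param range_means named numeric vector: true means (mmHg) for which the
#'   report illustrates the 95% reading range, named by the CoV parameter to
#'   use (e.g. `c(sbp_day = 140, dbp_day = 90)`).
#' @param seed root random seed for simulation-backed stages.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(rules = validity_rules(),
                            coverage = 0.95,
                            ci_method = c("delta", "chisq"),
                            bonferroni = c("pairwise", "single"),
                            ht_threshold = 135,
                            range_means = c(sbp_day = 140, dbp_day = 90),
                            seed = 1L) {
  stopifnot(inherits(rules, "validity_rules"),
            coverage > 0, coverage < 1, ht_threshold > 0)
  structure(list(
    rules = rules,
    coverage = coverage,
    ci_method = match.arg(ci_method),
    bonferroni = match.arg(bonferroni),
    ht_threshold = ht_threshold,
    range_means = range_means,
    seed = as.integer(seed)
  ), class = "analysis_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' Accepts a file holding any subset of the [analysis_config()] fields
#' (nested `rules` fields included); unspecified fields keep their defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return an `analysis_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  rule_args <- raw$rules %||% list()
  rules <- do.call(validity_rules, rule_args)
  args <- raw[setdiff(names(raw), "rules")]
  args <- args[names(args) %in% names(formals(analysis_config))]
  if (!is.null(args$range_means)) args$range_means <- unlist(args$range_means)
  do.call(analysis_config, c(list(rules = rules), args))
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("ABPM analysis configuration\n")
  cat(sprintf("  CI coverage: %.2f (%s method)\n", x$coverage, x$ci_method))
  cat(sprintf("  Bonferroni family: %s\n", x$bonferroni))
  cat(sprintf("  Hypertension threshold: baseline daytime SBP >= %g mmHg\n",
              x$ht_threshold))
  cat(sprintf("  Validity: SBP [%g, %g], DBP [%g, %g], HR [%g, %g], min counts %d day / %d night\n",
              x$rules$sbp_bounds[1], x$rules$sbp_bounds[2],
              x$rules$dbp_bounds[1], x$rules$dbp_bounds[2],
              x$rules$hr_bounds[1], x$rules$hr_bounds[2],
              x$rules$min_day, x$rules$min_night))
  invisible(x)
}
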