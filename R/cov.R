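#' Within-individual coefficient of variation (logarithmic method)
#'
#' Estimates the within-individual coefficient of variation (CoV) of a
#' positive, repeatedly measured quantity — session-level blood pressure
#' means, heart rate, or pulse wave velocity — by pooling the within-subject
#' variance of the natural-log transformed measurements across individuals
#' (the Bland–Altman logarithmic method).
#'
#' With `x_ij = log(y_ij)` for individual `i`, session `j`, the pooled
#' within-subject variance is
#' \deqn{s_w^2 = \sum_i \sum_j (x_{ij} - \bar x_i)^2 / \sum_i (m_i - 1),}
#' taken over individuals with at least two sessions (unbalanced designs are
#' allowed; individuals with a single session are excluded and counted but
#' never affect the estimate). The CoV is the exact lognormal mapping
#' \deqn{CoV = 100 \sqrt{\exp(s_w^2) - 1}\ \%.}
#' Because the model is multiplicative, the estimate is invariant to
#' rescaling all measurements by a positive constant.
#'
#' The default confidence interval uses the large-sample standard error of a
#' pooled SD, `se(s_w) = s_w / sqrt(2 df)` with `df = sum(m_i - 1)`
#' (equivalently total sessions minus individuals, over retained
#' individuals), forms normal-quantile bounds for `s_w`, and maps them
#' through the same CoV transform. `ci_method = "chisq"` instead uses the
#' chi-square pivot for `df * s_w^2 / sigma^2`.
#'
#' @param values positive numeric measurements, one element per session.
#' @param id individual identifier, parallel to `values`.
#' @param coverage confidence-interval coverage (default 0.95).
#' @param ci_method `"delta"` (default) or `"chisq"`; see Details.
#' @param parameter,group optional labels carried into the result and its
#'   printed form (e.g. `"sbp_day"`, `"normotensive"`).
#' @return An object of class `cov_within`: a list with `cov_pct`, `ci_lo`,
#'   `ci_hi`, `s_w` (log-scale within-subject SD), `df`, `n_individuals`
#'   (retained, i.e. with >= 2 sessions), `n_excluded` (single-session
#'   individuals), `n_sessions_total`, `coverage`, plus the labels.
#' @examples
#' vals <- c(100, 110, 90, 110)
#' ids <- c("A", "A", "B", "B")
#' cov_within(vals, ids)
#' @seealso [compare_cov()], [reference_range()], [individual_bpv()]
#' @export
cov_within <- function(values, id, coverage = 0.95,
                       ci_method = c("delta", "chisq"),
                       parameter = NA_character_, group = "all") {
  ci_method <- match.arg(ci_method)
  stopifnot(length(values) == length(id), coverage > 0, coverage < 1)
  keep <- !is.na(values) & !is.na(id)
  values <- values[keep]; id <- id[keep]
  if (any(values <= 0)) {
    stop("all values must be strictly positive for the log transformation",
         call. = FALSE)
  }
  x <- log(values)
  m <- tapply(x, id, length)
  if (!any(m >= 2L)) {
    stop("insufficient data: no individual has >= 2 sessions", call. = FALSE)
  }
  retained <- names(m)[m >= 2L]
  in_ret <- id %in% retained
  xr <- x[in_ret]; idr <- factor(id[in_ret])
  centred <- xr - ave(xr, idr)
  df <- length(xr) - nlevels(idr)
  s2w <- sum(centred^2) / df
  s_w <- sqrt(s2w)

  z <- stats::qnorm((1 + coverage) / 2)
  if (s_w == 0) {
    sw_lo <- sw_hi <- 0
  } else if (ci_method == "delta") {
    se <- s_w / sqrt(2 * df)
    sw_lo <- max(0, s_w - z * se)
    sw_hi <- s_w + z * se
  } else {
    a <- (1 - coverage) / 2
    sw_lo <- sqrt(df * s2w / stats::qchisq(1 - a, df))
    sw_hi <- sqrt(df * s2w / stats::qchisq(a, df))
  }

  structure(list(
    parameter = parameter, group = group,
    cov_pct = cov_from_sigma_w(s_w),
    ci_lo = cov_from_sigma_w(sw_lo),
    ci_hi = cov_from_sigma_w(sw_hi),
    s_w = s_w, df = df,
    n_individuals = length(retained),
    n_excluded = sum(m < 2L),
    n_sessions_total = length(xr),
    coverage = coverage, ci_method = ci_method
  ), class = "cov_within")
}

#' @export
print.cov_within <- function(x, ...) {
  lab <- if (is.na(x$parameter)) "" else paste0(" [", x$parameter,
                                                if (!identical(x$group, "all"))
                                                  paste0(", ", x$group), "]")
  cat(sprintf("Within-individual CoV%s: %s%%\n", lab,
              fmt_cov_ci(x$cov_pct, x$ci_lo, x$ci_hi)))
  cat(sprintf("  s_w (log scale) = %.5f, df = %d, %d individuals, %d sessions",
              x$s_w, x$df, x$n_individuals, x$n_sessions_total))
  if (x$n_excluded > 0)
    cat(sprintf(" (%d single-session individuals excluded)", x$n_excluded))
  cat("\n")
  invisible(x)
}

#' @export
confint.cov_within <- function(object, parm, level, ...) {
  out <- matrix(c(object$ci_lo, object$ci_hi), 1L, 2L,
                dimnames = list("cov_pct",
                                sprintf("%.1f %%", 100 * c(
                                  (1 - object$coverage) / 2,
                                  (1 + object$coverage) / 2))))
  out
}

#' Compare two within-individual CoV estimates
#'
#' Reports two complementary verdicts on whether measurement variability
#' differs between groups (e.g. normotensive vs hypertensive individuals):
#' (i) whether the two confidence intervals overlap (conservative), and
#' (ii) an asymptotic z-test on the log-scale within-subject SDs using
#' `se(s_w) = s_w / sqrt(2 df)` per group.
#'
#' @param a,b `cov_within` objects for the same parameter.
#' @return object of class `cov_comparison` with `ci_overlap`, `z`, `p`
#'   (two-sided; both `NA` when either group has zero `s_w`).
#' @export
compare_cov <- function(a, b) {
  stopifnot(inherits(a, "cov_within"), inherits(b, "cov_within"))
  overlap <- !(a$ci_lo > b$ci_hi || b$ci_lo > a$ci_hi)
  if (a$s_w == 0 || b$s_w == 0) {
    z <- p <- NA_real_
  } else {
    se <- sqrt(a$s_w^2 / (2 * a$df) + b$s_w^2 / (2 * b$df))
    z <- (a$s_w - b$s_w) / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(
    parameter = a$parameter, group_a = a$group, group_b = b$group,
    cov_a = a$cov_pct, cov_b = b$cov_pct,
    ci_overlap = overlap, z = z, p = p
  ), class = "cov_comparison")
}

#' @export
print.cov_comparison <- function(x, ...) {
  cat(sprintf("CoV comparison%s: %s %.1f%% vs %s %.1f%%\n",
              if (is.na(x$parameter)) "" else paste0(" [", x$parameter, "]"),
              x$group_a, x$cov_a, x$group_b, x$cov_b))
  cat(sprintf("  95%% CI overlap: %s\n", if (x$ci_overlap) "yes" else "no"))
  if (is.na(x$z)) {
    cat("  z-test undefined (zero within-subject SD in a group)\n")
  } else {
    cat(sprintf("  z = %.3f, two-sided p = %.4g (asymptotic, on log-scale SDs)\n",
                x$z, x$p))
  }
  invisible(x)
}

#' Per-individual blood pressure variability records
#'
#' For each individual and parameter, the arithmetic mean and sample SD
#' (denominator n-1) of that individual's session-level means, plus the
#' individual CoV (SD/mean). The intra-individual SD is the working
#' definition of blood pressure variability (BPV) used by the regression
#' models; individuals with fewer than two sessions are excluded.
#'
#' @param sessions session-level data frame (schema of `sessions.csv`).
#' @param parameters character vector of session columns to summarize.
#' @param min_sessions minimum sessions per retained individual (default 2).
#' @return data frame with columns `individual_id`, `parameter`, `mean`,
#'   `sd`, `individual_cov`, `n_sessions`; attribute `n_excluded` counts
#'   dropped individuals, attribute `summary` holds the cohort mean and SD
#'   of the per-individual SDs by parameter.
#' @examples
#' s <- data.frame(individual_id = c("A", "A"), sbp_day = c(120, 130))
#' individual_bpv(s, "sbp_day")
#' @export
individual_bpv <- function(sessions,
                           parameters = c("sbp_day", "sbp_night",
                                          "dbp_day", "dbp_night"),
                           min_sessions = 2L) {
  stopifnot(is.data.frame(sessions), "individual_id" %in% names(sessions))
  missing_cols <- setdiff(parameters, names(sessions))
  if (length(missing_cols))
    stop("sessions lack columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  out <- do.call(rbind, lapply(parameters, function(p) {
    v <- sessions[[p]]
    ok <- !is.na(v)
    sp <- split(v[ok], sessions$individual_id[ok])
    sp <- sp[vapply(sp, length, 1L) >= min_sessions]
    if (!length(sp)) return(NULL)
    data.frame(
      individual_id = names(sp),
      parameter = p,
      mean = vapply(sp, mean, 1),
      sd = vapply(sp, stats::sd, 1),
      n_sessions = vapply(sp, length, 1L),
      row.names = NULL
    )
  }))
  if (is.null(out))
    stop("insufficient data: no individual has >= ", min_sessions,
         " sessions for any parameter", call. = FALSE)
  out$individual_cov <- ifelse(out$mean > 0, out$sd / out$mean, NA_real_)
  out <- out[c("individual_id", "parameter", "mean", "sd",
               "individual_cov", "n_sessions")]
  n_ids <- length(unique(sessions$individual_id))
  attr(out, "n_excluded") <- n_ids - length(unique(out$individual_id))
  sm <- do.call(rbind, lapply(split(out, out$parameter), function(d) {
    data.frame(parameter = d$parameter[1], sd_mean = mean(d$sd),
               sd_sd = stats::sd(d$sd), n = nrow(d), row.names = NULL)
  }))
  attr(out, "summary") <- sm
  out
}

#' Expected 95% reading range around a true mean
#'
#' Given an individual's true average pressure and a measurement CoV, the
#' interval within which the stated fraction of single-session measurements
#' is expected to fall under the normal approximation:
#' `mean * (1 -/+ z * CoV/100)` with `z` the normal quantile at
#' `(1 + coverage)/2`. Reports present the bounds rounded to integer units
#' (e.g. a true daytime systolic of 140 mmHg with CoV 5.4% gives 125–155).
#'
#' @param true_mean true average value (> 0), e.g. mmHg.
#' @param cov_pct coefficient of variation in percent (>= 0).
#' @param coverage fraction of readings the range should contain.
#' @return object of class `reference_range`: `lo`, `hi` (exact bounds) and
#'   `presented` (integer-rounded "lo–hi" string).
#' @examples
#' reference_range(140, 5.4)
#' @export
reference_range <- function(true_mean, cov_pct, coverage = 0.95) {
  stopifnot(length(true_mean) == 1L, length(cov_pct) == 1L,
            coverage > 0, coverage < 1)
  if (true_mean <= 0) stop("true_mean must be positive", call. = FALSE)
  if (cov_pct < 0) stop("cov_pct must be non-negative", call. = FALSE)
  z <- stats::qnorm((1 + coverage) / 2)
  lo <- true_mean * (1 - z * cov_pct / 100)
  hi <- true_mean * (1 + z * cov_pct / 100)
  if (lo <= 0) {
    stop("CoV too large: lower bound of the reading range is not positive",
         call. = FALSE)
  }
  structure(list(true_mean = true_mean, cov_pct = cov_pct,
                 coverage = coverage, lo = lo, hi = hi,
                 presented = fmt_range(lo, hi)),
            class = "reference_range")
}

#' @export
print.reference_range <- function(x, ...) {
  cat(sprintf("%.0f%% of readings around a true mean of %g (CoV %.1f%%): %s\n",
              100 * x$coverage, x$true_mean, x$cov_pct, x$presented))
  invisible(x)
}
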