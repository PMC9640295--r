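#' One-way repeated-measures ANOVA
#'
#' Within-subject decomposition for a complete subjects-by-timepoints
#' matrix: `SS_total = SS_subjects + SS_time + SS_residual`, with
#' `F = MS_time / MS_residual` on `(t - 1)` and `(t - 1)(n - 1)` degrees of
#' freedom and the sphericity-assumed p-value (no Greenhouse–Geisser type
#' correction is applied by default, mirroring a plain SPSS-style analysis).
#' Rows containing any missing value are dropped and counted.
#'
#' @param mat numeric matrix, subjects in rows, timepoints in columns.
#' @return object of class `rm_anova`: `F`, `df_num`, `df_den`, `p`,
#'   per-timepoint `means`, the SS table, `n_subjects` (complete),
#'   `n_dropped`.
#' @examples
#' m <- matrix(rnorm(20, 120, 5), 5, 4)
#' rm_anova(m)
#' @export
rm_anova <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need at least 2 timepoints", call. = FALSE)
  complete <- stats::complete.cases(mat)
  n_dropped <- sum(!complete)
  mat <- mat[complete, , drop = FALSE]
  n <- nrow(mat); t <- ncol(mat)
  if (n < 3L) stop("insufficient data: fewer than 3 complete subjects",
                   call. = FALSE)
  grand <- mean(mat)
  ss_subj <- t * sum((rowMeans(mat) - grand)^2)
  ss_time <- n * sum((colMeans(mat) - grand)^2)
  ss_total <- sum((mat - grand)^2)
  ss_res <- ss_total - ss_subj - ss_time
  df_num <- t - 1L
  df_den <- (t - 1L) * (n - 1L)
  if (ss_time <= 0) {
    Fst <- 0; p <- 1
  } else {
    Fst <- (ss_time / df_num) / (ss_res / df_den)
    p <- stats::pf(Fst, df_num, df_den, lower.tail = FALSE)
  }
  structure(list(F = Fst, df_num = df_num, df_den = df_den, p = p,
                 means = colMeans(mat),
                 ss = c(subjects = ss_subj, time = ss_time,
                        residual = ss_res, total = ss_total),
                 n_subjects = n, n_dropped = n_dropped),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%d, %d) = %.4f, p = %.4g (%d subjects",
              x$df_num, x$df_den, x$F, x$p, x$n_subjects))
  if (x$n_dropped > 0) cat(sprintf(", %d incomplete dropped", x$n_dropped))
  cat(")\n  timepoint means:",
      paste(sprintf("%.2f", x$means), collapse = ", "), "\n")
  invisible(x)
}

#' Screen a study arm for stability across sessions
#'
#' The eligibility rule for pooling an arm into the reproducibility
#' analysis: run the repeated-measures ANOVA across sessions; the arm is
#' eligible outright when the overall p exceeds 0.05. Otherwise a paired
#' t-test compares the first and last session, Bonferroni-adjusted — by
#' default over the full family of `t(t-1)/2` pairwise timepoint
#' comparisons (capped at 1); `bonferroni = "single"` uses multiplier 1 —
#' and the arm remains eligible when the adjusted p is at least 0.05 (no
#' demonstrable first-to-last shift).
#'
#' @param mat complete-case subjects x sessions matrix for one arm and one
#'   parameter.
#' @param bonferroni `"pairwise"` (default) or `"single"`; see above.
#' @param alpha significance level of the screen (default 0.05).
#' @return object of class `arm_eligibility`: `anova_p`, `posthoc_p`
#'   (adjusted; `NA` when not run), `eligible`, `reason`, `multiplier`.
#' @export
screen_arm_eligibility <- function(mat, bonferroni = c("pairwise", "single"),
                                   alpha = 0.05) {
  bonferroni <- match.arg(bonferroni)
  a <- rm_anova(mat)
  t <- a$df_num + 1L
  mult <- if (bonferroni == "pairwise") t * (t - 1L) / 2 else 1
  if (a$p > alpha) {
    res <- list(anova_p = a$p, posthoc_p = NA_real_, eligible = TRUE,
                reason = "no significant change across sessions",
                multiplier = mult)
  } else {
    mat <- as.matrix(mat)
    mat <- mat[stats::complete.cases(mat), , drop = FALSE]
    pt <- paired_t(mat[, ncol(mat)], mat[, 1L])
    p_adj <- min(1, pt$p * mult)
    res <- list(anova_p = a$p, posthoc_p = p_adj,
                eligible = p_adj >= alpha,
                reason = if (p_adj >= alpha)
                  "overall change but no first-vs-last difference"
                else "significant first-vs-last change",
                multiplier = mult)
  }
  structure(res, class = "arm_eligibility")
}

#' @export
print.arm_eligibility <- function(x, ...) {
  cat(sprintf("Arm eligibility: %s (ANOVA p = %.4g",
              if (x$eligible) "ELIGIBLE" else "NOT ELIGIBLE", x$anova_p))
  if (!is.na(x$posthoc_p)) {
    cat(sprintf("; first-vs-last Bonferroni-adjusted p = %.4g, multiplier %g",
                x$posthoc_p, x$multiplier))
  }
  cat(")\n  ", x$reason, "\n", sep = "")
  invisible(x)
}

#' Paired t-test
#'
#' Thin wrapper around [stats::t.test()] for paired samples with the
#' degenerate cases pinned down: all differences zero gives `t = 0, p = 1`;
#' constant non-zero differences (zero variance) are reported with
#' `p = 0` by convention.
#'
#' @param x,y paired numeric vectors; pairs with a missing member are
#'   dropped.
#' @return list with `t`, `df`, `p`, `mean_diff`, `n`.
#' @export
paired_t <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, df = length(d) - 1L, p = 1, mean_diff = 0,
                  n = length(d)))
    }
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1L, p = 0,
                mean_diff = mean(d), n = length(d)))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate), n = length(d))
}

#' Pearson correlation with two-sided p
#'
#' Wrapper around [stats::cor.test()]; errors on degenerate input rather
#' than returning `NA` silently.
#'
#' @param x,y numeric vectors; incomplete pairs dropped.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: a variable has zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Multivariable linear regression with standardized coefficients
#'
#' Ordinary least squares with all predictors entered simultaneously (the
#' "enter" method), reporting for each predictor the raw coefficient, the
#' standardized coefficient `beta = b * sd(x) / sd(y)` (binary predictors
#' coded 0/1 and scaled the same way), and the two-sided p from the t
#' statistic. Listwise deletion is applied first.
#'
#' @param formula model formula.
#' @param data data frame.
#' @return object of class `ols_std`: `coefficients` data frame (term, `b`,
#'   `beta`, `se`, `p`), `n`, `r_squared`, and the underlying `lm` fit.
#' @examples
#' d <- data.frame(y = rnorm(20), x = rnorm(20))
#' ols_std(y ~ x, d)
#' @export
ols_std <- function(formula, data) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  fit <- stats::lm(formula, data = mf)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  X <- stats::model.matrix(fit)
  y <- stats::model.response(mf)
  terms <- setdiff(colnames(X), "(Intercept)")
  b <- stats::coef(fit)[terms]
  sx <- apply(X[, terms, drop = FALSE], 2, stats::sd)
  beta <- b * sx / stats::sd(y)
  ct <- sm$coefficients[terms, , drop = FALSE]
  structure(list(
    coefficients = data.frame(term = terms, b = unname(b),
                              beta = unname(beta),
                              se = unname(ct[, "Std. Error"]),
                              p = unname(ct[, "Pr(>|t|)"]),
                              row.names = NULL),
    n = nrow(X), r_squared = sm$r.squared, fit = fit
  ), class = "ols_std")
}

#' @export
print.ols_std <- function(x, digits = 3, ...) {
  cat(sprintf("Standardized-coefficient OLS (n = %d, R^2 = %.3f)\n",
              x$n, x$r_squared))
  tab <- x$coefficients
  tab$b <- signif(tab$b, digits); tab$beta <- signif(tab$beta, digits)
  tab$se <- signif(tab$se, digits); tab$p <- signif(tab$p, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Regression models of blood pressure variability on individual risk factors
#'
#' Builds the four BPV determinant models: the outcome is each individual's
#' session SD of `sbp_day`, `sbp_night`, `dbp_day` and `dbp_night`
#' (one model per parameter), and the predictors are age, sex, white vs
#' other ethnicity, baseline BMI, baseline PWV, antihypertensive use, plus
#' the individual's mean systolic and diastolic pressures of the matching
#' period (day models get day means, night models night means).
#' Individuals with any missing covariate are dropped listwise from the
#' regression only.
#'
#' @param cohort an `abpm_cohort` with sessions.
#' @param sleep_duration optional named numeric vector (hours, names =
#'   individual ids): appended as an extra predictor to the night models
#'   (the sleep-duration sensitivity analysis).
#' @return named list of [ols_std()] fits, one per BPV outcome.
#' @export
bpv_regression <- function(cohort, sleep_duration = NULL) {
  stopifnot(inherits(cohort, "abpm_cohort"), !is.null(cohort$sessions))
  params <- c("sbp_day", "sbp_night", "dbp_day", "dbp_night")
  bpv <- individual_bpv(cohort$sessions, params)
  ind <- cohort$individuals
  base <- data.frame(
    individual_id = ind$individual_id,
    age = ind$age,
    sex_male = as.numeric(ind$sex == "male"),
    ethnicity_white = as.numeric(ind$ethnicity_white),
    bmi = ind$bmi,
    pwv = ind$pwv_v1,
    antihypertensive = as.numeric(ind$antihypertensive)
  )
  wide_stat <- function(stat, p) {
    d <- bpv[bpv$parameter == p, ]
    d[[stat]][match(base$individual_id, d$individual_id)]
  }
  fits <- list()
  for (p in params) {
    period <- if (grepl("night", p)) "night" else "day"
    d <- base
    d$outcome <- wide_stat("sd", p)
    d$mean_sbp <- wide_stat("mean", paste0("sbp_", period))
    d$mean_dbp <- wide_stat("mean", paste0("dbp_", period))
    rhs <- c("age", "sex_male", "ethnicity_white", "bmi", "pwv",
             "antihypertensive", "mean_sbp", "mean_dbp")
    if (!is.null(sleep_duration) && period == "night") {
      d$sleep_duration <- sleep_duration[match(d$individual_id,
                                               names(sleep_duration))]
      rhs <- c(rhs, "sleep_duration")
    }
    f <- stats::reformulate(rhs, response = "outcome")
    fits[[paste0(p, "_sd")]] <- ols_std(f, d)
  }
  fits
}

#' Fleiss' kappa for multi-session categorical agreement
#'
#' Chance-corrected agreement among a fixed number of categorical ratings
#' per subject — here, repeated ABPM sessions acting as "raters" of an
#' individual's dipping category. Uses the standard formulation: category
#' proportions `p_j`, per-subject agreement
#' `P_i = (sum_j n_ij^2 - n) / (n (n - 1))`,
#' `kappa = (P_bar - P_e) / (1 - P_e)` with `P_e = sum p_j^2`, and the
#' large-sample null variance for the z test. Subjects with missing
#' ratings are excluded (count reported), since the statistic requires an
#' equal number of ratings per subject.
#'
#' @param ratings matrix or data frame of categories, subjects in rows,
#'   sessions (raters) in columns.
#' @param categories optional vector of category levels (defaults to the
#'   levels observed).
#' @return object of class `fleiss_kappa`: `kappa`, `z`, `p`, `n_subjects`,
#'   `n_raters`, `categories`, `n_excluded`.
#' @examples
#' r <- rbind(c("A", "A"), c("A", "B"), c("B", "B"))
#' fleiss_kappa(r)
#' @export
fleiss_kappa <- function(ratings, categories = NULL) {
  ratings <- as.matrix(ratings)
  complete <- stats::complete.cases(ratings)
  n_excluded <- sum(!complete)
  ratings <- ratings[complete, , drop = FALSE]
  if (nrow(ratings) < 2L) {
    stop("need at least 2 subjects with complete ratings", call. = FALSE)
  }
  n_r <- ncol(ratings)
  if (n_r < 2L) stop("need at least 2 ratings per subject", call. = FALSE)
  categories <- categories %||% sort(unique(as.vector(ratings)))
  counts <- t(apply(ratings, 1L, function(row) {
    tabulate(factor(row, levels = categories), nbins = length(categories))
  }))
  N <- nrow(counts)
  p_j <- colSums(counts) / (N * n_r)
  P_i <- (rowSums(counts^2) - n_r) / (n_r * (n_r - 1))
  P_bar <- mean(P_i)
  P_e <- sum(p_j^2)
  if (1 - P_e < .Machine$double.eps) {
    stop("kappa undefined: all ratings fall in a single category",
         call. = FALSE)
  }
  kappa <- (P_bar - P_e) / (1 - P_e)
  # large-sample variance under the null (Fleiss 1971)
  var0 <- 2 / (N * n_r * (n_r - 1)) *
    (P_e - (2 * n_r - 3) * P_e^2 + 2 * (n_r - 2) * sum(p_j^3)) / (1 - P_e)^2
  z <- kappa / sqrt(var0)
  structure(list(kappa = kappa, z = z, p = 2 * stats::pnorm(-abs(z)),
                 n_subjects = N, n_raters = n_r, categories = categories,
                 n_excluded = n_excluded),
            class = "fleiss_kappa")
}

#' @export
print.fleiss_kappa <- function(x, ...) {
  cat(sprintf("Fleiss' kappa = %.3f (z = %.2f, p = %.4g; %d subjects x %d ratings",
              x$kappa, x$z, x$p, x$n_subjects, x$n_raters))
  if (x$n_excluded > 0) cat(sprintf("; %d incomplete excluded", x$n_excluded))
  cat(")\n")
  invisible(x)
}

#' Test for adaptation to the ABPM device
#'
#' Restricted to individuals carrying the full session count, runs the
#' repeated-measures ANOVA of a session parameter across session index and
#' reports the per-session means — the pattern of interest being a
#' first-session pressor effect with regression to the mean on later
#' sessions.
#'
#' @param sessions sessions data frame.
#' @param parameter session column to test (e.g. `"dbp_night"`).
#' @param n_required sessions an individual must have to enter (default:
#'   the maximum observed).
#' @return `rm_anova` object, with the subset size in `n_subjects`.
#' @export
adaptation_test <- function(sessions, parameter, n_required = NULL) {
  stopifnot(parameter %in% names(sessions))
  counts <- table(sessions$individual_id)
  n_required <- n_required %||% max(counts)
  keep <- names(counts)[counts == n_required]
  s <- sessions[sessions$individual_id %in% keep &
                  sessions$session_index <= n_required, ]
  mat <- matrix(NA_real_, length(keep), n_required,
                dimnames = list(keep, NULL))
  mat[cbind(match(s$individual_id, keep), s$session_index)] <- s[[parameter]]
  rm_anova(mat)
}
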