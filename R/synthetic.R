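# Hierarchical lognormal simulator for sequential-ABPM cohorts.
#
# Model: each individual i carries a latent true mean for every ambulatory
# parameter; session-level values are y_ij = exp(log(true_i) + sigma_w*eps_ij)
# with iid standard-normal eps — a multiplicative error model, chosen because
# within-individual SD scales with mean pressure and the reproducibility
# estimator works on log-transformed data. Between-individual log-SDs are
# back-solved so that observed baseline session values reproduce the target
# cohort marginals (observed variance = between + within on the log scale).

STUDY_TEMPLATES <- list(
  CRESSIDA = list(n = 159L, weeks = c(0, 3, 7, 11, 15)),
  FruitVeg = list(n = 48L,  weeks = c(0, 6, 17, 28, 39)),
  MARINA   = list(n = 294L, weeks = c(0, 26, 52))
)

# Between-individual marginals of baseline session values (mean, SD) and
# within-individual CoV targets (%), per ambulatory parameter.
AMBULATORY_MARGINALS <- data.frame(
  parameter = c("sbp_day", "sbp_night", "sbp_24h", "dbp_day", "dbp_night",
                "dbp_24h", "hr_day", "hr_night", "hr_24h", "pwv"),
  mean = c(130, 110, 125, 79, 65, 76, 75, 63, 72, 8.4),
  sd   = c(13, 14, 13, 8, 8, 7, 8, 9, 8, 1.6),
  cov  = c(5.4, 7.0, 4.8, 6.1, 8.4, 5.3, 6.3, 7.9, 5.9, 10.7)
)

# Order of the jointly drawn variables: two raw-scale covariates, then the
# log-scale latent means of PWV and the six primary ambulatory parameters
# (24-h values are derived, not drawn).
JOINT_VARS <- c("age", "bmi", "pwv", "sbp_day", "sbp_night",
                "dbp_day", "dbp_night", "hr_day", "hr_night")

#' Default cross-correlation targets for the cohort simulator
#'
#' Correlation matrix of the jointly drawn individual-level latents (age,
#' BMI, and the log-scale true means of PWV and the six day/night ambulatory
#' parameters). The covariate–pressure entries are the observed cohort
#' correlations the simulator reproduces; the within-pressure block (day
#' vs night, systolic vs diastolic, r = 0.5–0.7) and the age–PWV link are
#' physiologically conventional values that give realistic dipping spread
#' and arterial-stiffness structure without being fitted to anything.
#'
#' @param pwv_sbp_day,pwv_sbp_night,pwv_dbp_day,pwv_dbp_night PWV–pressure targets.
#' @param bmi_sbp_day,bmi_sbp_night,bmi_dbp_day,bmi_dbp_night BMI–pressure targets.
#' @param age_sbp_day,age_sbp_night,age_dbp_day,age_dbp_night age–pressure targets.
#' @param day_night within-parameter day/night correlation.
#' @param sbp_dbp same-period systolic/diastolic correlation.
#' @param age_pwv,age_bmi,bmi_pwv covariate block.
#' @param hr_bp heart-rate to pressure correlation.
#' @return 9 x 9 correlation matrix over `age, bmi, pwv, sbp_day, sbp_night,
#'   dbp_day, dbp_night, hr_day, hr_night`.
#' @export
default_correlations <- function(pwv_sbp_day = 0.40, pwv_sbp_night = 0.41,
                                 pwv_dbp_day = 0.25, pwv_dbp_night = 0.30,
                                 bmi_sbp_day = 0.26, bmi_sbp_night = 0.29,
                                 bmi_dbp_day = 0.16, bmi_dbp_night = 0.23,
                                 age_sbp_day = 0.15, age_sbp_night = 0.14,
                                 age_dbp_day = 0.02, age_dbp_night = 0.05,
                                 day_night = 0.70, sbp_dbp = 0.70,
                                 age_pwv = 0.35, age_bmi = 0.10,
                                 bmi_pwv = 0.15, hr_bp = 0.10) {
  R <- diag(9)
  dimnames(R) <- list(JOINT_VARS, JOINT_VARS)
  set_r <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  set_r("age", "bmi", age_bmi); set_r("age", "pwv", age_pwv)
  set_r("bmi", "pwv", bmi_pwv)
  set_r("age", "sbp_day", age_sbp_day); set_r("age", "sbp_night", age_sbp_night)
  set_r("age", "dbp_day", age_dbp_day); set_r("age", "dbp_night", age_dbp_night)
  set_r("bmi", "sbp_day", bmi_sbp_day); set_r("bmi", "sbp_night", bmi_sbp_night)
  set_r("bmi", "dbp_day", bmi_dbp_day); set_r("bmi", "dbp_night", bmi_dbp_night)
  set_r("pwv", "sbp_day", pwv_sbp_day); set_r("pwv", "sbp_night", pwv_sbp_night)
  set_r("pwv", "dbp_day", pwv_dbp_day); set_r("pwv", "dbp_night", pwv_dbp_night)
  set_r("sbp_day", "sbp_night", day_night)
  set_r("dbp_day", "dbp_night", day_night)
  set_r("hr_day", "hr_night", day_night)
  set_r("sbp_day", "dbp_day", sbp_dbp)
  set_r("sbp_night", "dbp_night", sbp_dbp)
  set_r("sbp_day", "dbp_night", 0.50)
  set_r("sbp_night", "dbp_day", 0.50)
  for (v in c("sbp_day", "sbp_night", "dbp_day", "dbp_night")) {
    set_r("hr_day", v, hr_bp); set_r("hr_night", v, hr_bp)
  }
  R
}

#' Cohort simulation specification
#'
#' Everything the simulator needs: study templates (sample sizes and visit
#' schedules of the three emulated trials), covariate marginals, baseline
#' marginals and within-individual CoV targets for each ambulatory
#' parameter, cross-correlation targets, reading-level noise, and the
#' optional device-adaptation effect on night-time diastolic pressure.
#' Defaults reproduce the emulated cohort: 501 individuals (CRESSIDA 159
#' with 5 visits, Fruit & Veg 48 with 5 visits, MARINA 294 with 3 visits).
#'
#' @param n_per_study named integer vector of individuals per study
#'   template; names must be among `CRESSIDA`, `FruitVeg`, `MARINA`.
#' @param marginals data frame with columns `parameter`, `mean`, `sd`,
#'   `cov` (CoV target in percent) for the ten measured parameters.
#' @param corr correlation matrix over `age, bmi, pwv` and the six primary
#'   ambulatory parameters (see [default_correlations()]).
#' @param age_mean,age_sd,bmi_mean,bmi_sd covariate marginals.
#' @param p_female,p_antihypertensive prevalence of female sex and of
#'   antihypertensive use.
#' @param p_ethnicity named probabilities over `white, black, asian, other`.
#' @param clinic_corr correlation of clinic seated SBP/DBP/HR with the
#'   matching daytime ambulatory latent.
#' @param adaptation list with `enabled` and `offsets`: additive mmHg
#'   offsets applied to night-time DBP by session index (a device
#'   adaptation/regression-to-the-mean effect); off by default.
#' @param pwv_endpoint_shift additive change (m/s) in the true PWV mean at
#'   the final visit, interpolated linearly across visits; 0 by default.
#' @param session_factor_sd log-scale SD of a shared per-session factor
#'   added to every parameter of that session (a "high day" effect);
#'   0 by default (session errors independent across parameters).
#' @param reading_noise named SD vector for reading-level noise around the
#'   session latent, in measurement units (`sbp`, `dbp` mmHg; `hr` bpm).
#' @param p_missing probability a scheduled cuff reading is missing.
#' @param night_step_min,day_step_min device cadence (minutes) for the
#'   clock-night (22:00–07:00) and clock-day (07:00–22:00) schedule.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_study = c(CRESSIDA = 159L, FruitVeg = 48L,
                                        MARINA = 294L),
                        marginals = AMBULATORY_MARGINALS,
                        corr = default_correlations(),
                        age_mean = 53.4, age_sd = 8.0,
                        bmi_mean = 26.0, bmi_sd = 3.9,
                        p_female = 0.61,
                        p_ethnicity = c(white = 0.80, black = 0.08,
                                        asian = 0.09, other = 0.03),
                        p_antihypertensive = 0.02,
                        clinic_corr = 0.6,
                        adaptation = list(enabled = FALSE,
                                          offsets = c(-0.5, 0.5, 0.2, 0, -0.2)),
                        pwv_endpoint_shift = 0,
                        session_factor_sd = 0,
                        reading_noise = c(sbp = 9, dbp = 7, hr = 5),
                        p_missing = 0.08,
                        day_step_min = 30, night_step_min = 60) {
  stopifnot(all(names(n_per_study) %in% names(STUDY_TEMPLATES)),
            all(n_per_study >= 0),
            all(c("parameter", "mean", "sd", "cov") %in% names(marginals)),
            all(marginals$sd > 0), all(marginals$mean > 0),
            all(marginals$cov >= 0),
            is.matrix(corr), nrow(corr) == 9, ncol(corr) == 9,
            age_sd > 0, bmi_sd > 0,
            p_female >= 0, p_female <= 1,
            abs(sum(p_ethnicity) - 1) < 1e-8,
            p_missing >= 0, p_missing < 1,
            day_step_min >= 1, night_step_min >= 1)
  dimnames(corr) <- list(JOINT_VARS, JOINT_VARS)
  corr <- ensure_positive_definite(corr)
  spec <- structure(list(
    n_per_study = n_per_study, marginals = marginals, corr = corr,
    age_mean = age_mean, age_sd = age_sd, bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    p_female = p_female, p_ethnicity = p_ethnicity,
    p_antihypertensive = p_antihypertensive, clinic_corr = clinic_corr,
    adaptation = adaptation, pwv_endpoint_shift = pwv_endpoint_shift,
    session_factor_sd = session_factor_sd,
    reading_noise = reading_noise, p_missing = p_missing,
    day_step_min = day_step_min, night_step_min = night_step_min
  ), class = "cohort_spec")
  # fail early if any parameter's within-CoV exceeds its observed dispersion
  invisible(log_scale_components(spec))
  spec
}

# Nearest-PD repair by eigenvalue clipping; errors (naming the worst pair)
# if the repair moves any entry materially.
ensure_positive_definite <- function(R, tol = 0.05) {
  ok <- tryCatch({ chol(R); TRUE }, error = function(e) FALSE)
  if (ok) return(R)
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 1e-8)
  R2 <- e$vectors %*% diag(vals) %*% t(e$vectors)
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  delta <- abs(R2 - R)
  if (max(delta) > tol) {
    idx <- which(delta == max(delta), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "correlation targets are not positive definite; repair failed at pair (%s, %s)",
      rownames(R)[idx[1]], colnames(R)[idx[2]]), call. = FALSE)
  }
  dimnames(R2) <- dimnames(R)
  R2
}

# Log-scale decomposition per parameter: observed (baseline) log variance,
# within-individual log variance from the CoV target, and the implied
# between-individual component.
log_scale_components <- function(spec) {
  m <- spec$marginals
  sigma_obs2 <- log(1 + (m$sd / m$mean)^2)
  sigma_w2 <- log(1 + (m$cov / 100)^2)
  sigma_b2 <- sigma_obs2 - sigma_w2
  if (any(sigma_b2 <= 0)) {
    bad <- m$parameter[sigma_b2 <= 0]
    stop("within-individual CoV exceeds total dispersion for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  data.frame(parameter = m$parameter,
             mu_log = log(m$mean) - sigma_obs2 / 2,
             sigma_b = sqrt(sigma_b2), sigma_w = sqrt(sigma_w2),
             row.names = m$parameter)
}

# Correlation targets are stated on the raw measurement scale; the joint
# draw happens on the latent (log) scale, where the exp transform attenuates
# correlations slightly. Back-solve the latent correlation for each pair so
# the raw-scale correlation of the true means hits the target exactly:
# normal-lognormal r = rho * sigma / sqrt(exp(sigma^2) - 1), and
# lognormal-lognormal r = (exp(rho si sj) - 1) / sqrt((e^{si^2}-1)(e^{sj^2}-1)).
latent_correlations <- function(R, sigma) {
  out <- R
  p <- nrow(R)
  for (i in seq_len(p - 1)) for (j in seq(i + 1, p)) {
    r <- R[i, j]
    if (r == 0) next
    si <- sigma[i]; sj <- sigma[j]
    rho <- if (is.na(si) && is.na(sj)) {
      r
    } else if (is.na(si)) {
      r * sqrt(exp(sj^2) - 1) / sj
    } else if (is.na(sj)) {
      r * sqrt(exp(si^2) - 1) / si
    } else {
      log(1 + r * sqrt((exp(si^2) - 1) * (exp(sj^2) - 1))) / (si * sj)
    }
    out[i, j] <- out[j, i] <- rho
  }
  out
}

# Physiological clipping bounds for latent true means (raw scale).
clip_truth <- function(value, parameter) {
  bounds <- switch(sub("_.*", "", parameter),
                   sbp = c(80, 220), dbp = c(40, 140),
                   hr = c(35, 160), pwv = c(3, 20))
  pmin(pmax(value, bounds[1]), bounds[2])
}

#' Generate individuals and their latent true states
#'
#' Draws covariates from the spec's marginals and the individual-level true
#' ambulatory means from a joint Gaussian model on the log scale whose
#' implied raw-scale baseline means/SDs match the spec marginals and whose
#' pairwise correlations with age, BMI and PWV hit the spec targets (a
#' Gaussian copula with attenuation-corrected latent correlations is the
#' back-solved linear-effects construction). 24-h true means blend day and
#' night with the device-cadence weights `(30 day + 9 night) / 39`. PWV is
#' measured once per visit: columns `pwv_v1..pwv_v5` carry per-visit values
#' drawn with the PWV within-individual log-SD (blank beyond the study's
#' visit count). Baseline hypertensive status is left `NA` here — it is
#' derived from the baseline *session*, not the latent mean (see
#' [simulate_cohort()]).
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; identical spec + seed gives identical output.
#' @return list with `individuals` (one row per individual, `individuals.csv`
#'   schema) and `truth` (latent true means per parameter, raw scale).
#' @export
generate_individuals <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(substream_seed(seed, "individuals"))
  comp <- log_scale_components(spec)
  n_study <- spec$n_per_study[spec$n_per_study > 0]
  n <- sum(n_study)
  study <- rep(names(n_study), n_study)
  id <- sprintf("ID%04d", seq_len(n))

  logged <- c("pwv", "sbp_day", "sbp_night", "dbp_day", "dbp_night",
              "hr_day", "hr_night")
  mu <- c(spec$age_mean, spec$bmi_mean, comp[logged, "mu_log"])
  sdv <- c(spec$age_sd, spec$bmi_sd, comp[logged, "sigma_b"])
  R_latent <- ensure_positive_definite(
    latent_correlations(spec$corr, c(NA, NA, comp[logged, "sigma_b"])))
  draws <- rmvn_corr(n, mu, sdv, R_latent)
  colnames(draws) <- JOINT_VARS

  base <- c("sbp_day", "sbp_night", "dbp_day", "dbp_night", "hr_day", "hr_night")
  truth <- data.frame(individual_id = id, study = study)
  for (p in base) truth[[p]] <- clip_truth(exp(draws[, p]), p)
  # 24-h true mean blends day and night with the device-cadence weights (30
  # half-hourly daytime readings vs 9 hourly night readings), matching the
  # pooled-readings 24-h convention of the session summarizer
  truth$sbp_24h <- (30 * truth$sbp_day + 9 * truth$sbp_night) / 39
  truth$dbp_24h <- (30 * truth$dbp_day + 9 * truth$dbp_night) / 39
  truth$hr_24h <- (30 * truth$hr_day + 9 * truth$hr_night) / 39
  truth$pwv <- clip_truth(exp(draws[, "pwv"]), "pwv")

  zscore <- function(v) (v - mean(v)) / stats::sd(v)
  rc <- spec$clinic_corr
  mix <- function(z, m, s) m + s * (rc * z + sqrt(1 - rc^2) * stats::rnorm(n))
  individuals <- data.frame(
    individual_id = id, study = study,
    arm = sample(c("control", "intervention"), n, replace = TRUE),
    age = draws[, "age"],
    sex = ifelse(stats::runif(n) < spec$p_female, "female", "male"),
    ethnicity = sample(names(spec$p_ethnicity), n, replace = TRUE,
                       prob = spec$p_ethnicity),
    bmi = draws[, "bmi"],
    antihypertensive = stats::runif(n) < spec$p_antihypertensive,
    clinic_sbp = mix(zscore(draws[, "sbp_day"]), 124, 16),
    clinic_dbp = mix(zscore(draws[, "dbp_day"]), 80, 10),
    clinic_hr = mix(zscore(draws[, "hr_day"]), 68, 9)
  )
  individuals$ethnicity_white <- individuals$ethnicity == "white"

  sw_pwv <- comp["pwv", "sigma_w"]
  max_visits <- 5L
  pwv_mat <- matrix(NA_real_, n, max_visits)
  for (i in seq_len(n)) {
    weeks <- STUDY_TEMPLATES[[study[i]]]$weeks
    k <- length(weeks)
    shift <- spec$pwv_endpoint_shift * (seq_len(k) - 1) / (k - 1)
    true_visit <- pmax(truth$pwv[i] + shift, 0.1)
    pwv_mat[i, seq_len(k)] <- exp(log(true_visit) +
                                    sw_pwv * stats::rnorm(k))
  }
  colnames(pwv_mat) <- paste0("pwv_v", seq_len(max_visits))
  individuals <- cbind(individuals, as.data.frame(pwv_mat))
  individuals$ht_status <- NA_character_
  list(individuals = individuals, truth = truth)
}

#' Generate session-level summaries from latent true states
#'
#' Session value for parameter p of individual i at visit j:
#' `y_ij = exp(log(true_i) + sigma_w_p * eps_ij)` with independent standard
#' normal draws per parameter per session (sigma_w back-solved from the
#' spec's CoV targets). Visit counts and week spacing follow each study
#' template. The 24-h value perturbs the blended 24-h true mean with its
#' own (smaller) sigma_w, keeping day/night/24-h internally coherent while
#' preserving 24-h reproducibility as the best of the three. If the
#' adaptation switch is on, the per-visit mmHg offsets are added to
#' night-time DBP after the multiplicative draw. Dipping fields are
#' populated with [classify_dipping()].
#'
#' @param indiv output of [generate_individuals()].
#' @param spec the same [cohort_spec()].
#' @param seed integer seed (independent substream from the individuals
#'   draw, so the same root seed can serve both).
#' @return data frame in the `sessions.csv` schema plus a `date` column.
#' @export
generate_sessions <- function(indiv, spec = cohort_spec(), seed = 1L) {
  stopifnot(is.list(indiv), !is.null(indiv$truth))
  set.seed(substream_seed(seed, "sessions"))
  comp <- log_scale_components(spec)
  truth <- indiv$truth
  params <- c("sbp_day", "sbp_night", "sbp_24h", "dbp_day", "dbp_night",
              "dbp_24h", "hr_day", "hr_night", "hr_24h")
  visits <- vapply(STUDY_TEMPLATES[truth$study],
                   function(t) length(t$weeks), 1L)
  rows <- rep(seq_len(nrow(truth)), visits)
  vidx <- sequence(visits)
  n_sess <- length(rows)
  weeks <- unlist(lapply(STUDY_TEMPLATES[truth$study], `[[`, "weeks"),
                  use.names = FALSE)
  out <- data.frame(
    individual_id = truth$individual_id[rows],
    session_id = sprintf("%s-S%d", truth$individual_id[rows], vidx),
    session_index = vidx,
    date = as.Date("2019-01-07") + round(weeks * 7)
  )
  shared <- if (spec$session_factor_sd > 0) {
    spec$session_factor_sd * stats::rnorm(n_sess)
  } else {
    numeric(n_sess)
  }
  for (p in params) {
    sw <- comp[p, "sigma_w"]
    out[[p]] <- exp(log(truth[[p]][rows]) + sw * stats::rnorm(n_sess) + shared)
  }
  if (isTRUE(spec$adaptation$enabled)) {
    off <- spec$adaptation$offsets
    k <- pmin(vidx, length(off))
    out$dbp_night <- out$dbp_night + off[k]
  }
  out$n_day <- 30L
  out$n_night <- 9L
  dip <- classify_dipping(out$sbp_day, out$sbp_night)
  out$dip_pct <- dip$dip_pct
  out$dip_binary <- dip$dip_binary
  out$dip_category <- dip$dip_category
  out$ok <- TRUE
  out
}

#' Generate raw cuff readings and sleep diaries
#'
#' Reconstructs the session-level latents with the same substream as
#' [generate_sessions()] (so readings are consistent with the session table
#' for the same root seed), then lays out the device schedule — one reading
#' per `day_step_min` minutes while the clock is in 07:00–22:00 and per
#' `night_step_min` otherwise, over 24 h of wear starting at 10:00 — and
#' draws each reading as the session's day or night latent (day/night by
#' the jittered diary window, sleep onset 23:00 +/- 1 h, wake 07:00 +/- 1 h)
#' plus independent Gaussian reading noise. Scheduled readings are then
#' dropped independently with probability `p_missing`.
#'
#' @param indiv output of [generate_individuals()].
#' @param spec the same [cohort_spec()].
#' @param seed integer root seed.
#' @return list with `readings` and `diary` data frames (schemas of
#'   `readings.csv` / `diary.csv`).
#' @export
generate_readings <- function(indiv, spec = cohort_spec(), seed = 1L) {
  if (spec$night_step_min < 1 || spec$day_step_min < 1) {
    stop("reading cadence must be at least 1 minute", call. = FALSE)
  }
  sessions <- generate_sessions(indiv, spec, seed)
  set.seed(substream_seed(seed, "readings"))
  noise <- spec$reading_noise
  res_readings <- vector("list", nrow(sessions))
  res_diary <- vector("list", nrow(sessions))
  for (s in seq_len(nrow(sessions))) {
    day0 <- as.POSIXct(paste(sessions$date[s], "00:00:00"), tz = "UTC")
    onset <- day0 + 23 * 3600 + stats::runif(1, -3600, 3600)
    wake <- day0 + 24 * 3600 + 7 * 3600 + stats::runif(1, -3600, 3600)
    # device schedule: 24 h of wear from 10:00
    t <- day0 + 10 * 3600
    t_end <- t + 24 * 3600
    ts <- c()
    while (t < t_end) {
      ts <- c(ts, t)
      hr_clock <- as.integer(format(t, "%H", tz = "UTC"))
      step <- if (hr_clock >= 7 && hr_clock < 22) spec$day_step_min
              else spec$night_step_min
      t <- t + step * 60
    }
    ts <- as.POSIXct(ts, origin = "1970-01-01", tz = "UTC")
    night <- ts >= onset & ts < wake
    nr <- length(ts)
    sbp <- ifelse(night, sessions$sbp_night[s], sessions$sbp_day[s]) +
      stats::rnorm(nr, 0, noise[["sbp"]])
    dbp <- ifelse(night, sessions$dbp_night[s], sessions$dbp_day[s]) +
      stats::rnorm(nr, 0, noise[["dbp"]])
    hr <- ifelse(night, sessions$hr_night[s], sessions$hr_day[s]) +
      stats::rnorm(nr, 0, noise[["hr"]])
    keep <- stats::runif(nr) >= spec$p_missing
    res_readings[[s]] <- data.frame(
      individual_id = sessions$individual_id[s],
      session_id = sessions$session_id[s],
      timestamp = ts[keep], sbp = sbp[keep], dbp = dbp[keep], hr = hr[keep])
    res_diary[[s]] <- data.frame(
      individual_id = sessions$individual_id[s],
      session_id = sessions$session_id[s],
      sleep_onset = onset, wake_time = wake)
  }
  list(readings = do.call(rbind, res_readings),
       diary = do.call(rbind, res_diary))
}

#' Simulate a full ABPM cohort
#'
#' Convenience wrapper: draws individuals and sessions (and optionally raw
#' readings + diaries), derives baseline hypertensive status from the
#' baseline session's daytime systolic mean (>= `ht_threshold` mmHg is
#' hypertensive, ties included), and returns an `abpm_cohort` ready for
#' [run_full_analysis()]. All randomness flows from the single root seed
#' through named substreams, so session draws do not shift when readings
#' are also requested.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer root seed.
#' @param readings also generate reading-level data (slower).
#' @param ht_threshold hypertension threshold in mmHg (default 135).
#' @return object of class `abpm_cohort`: list with `individuals`,
#'   `sessions`, optionally `readings` and `diary`, plus the latent `truth`
#'   table and the spec/seed used.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1L,
                            readings = FALSE, ht_threshold = 135) {
  gi <- generate_individuals(spec, seed)
  sessions <- generate_sessions(gi, spec, seed)
  gi$individuals$ht_status <- derive_ht_status(gi$individuals, sessions,
                                               ht_threshold)
  rd <- if (readings) generate_readings(gi, spec, seed) else NULL
  structure(list(
    individuals = gi$individuals, sessions = sessions,
    readings = rd$readings, diary = rd$diary,
    truth = gi$truth, spec = spec, seed = as.integer(seed)
  ), class = "abpm_cohort")
}

#' @export
print.abpm_cohort <- function(x, ...) {
  cat(sprintf("ABPM cohort: %d individuals, %d sessions",
              nrow(x$individuals), nrow(x$sessions)))
  if (!is.null(x$readings)) cat(sprintf(", %d readings", nrow(x$readings)))
  cat("\n")
  tab <- table(x$individuals$study)
  cat("  studies:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                          collapse = ", "), "\n")
  if (!all(is.na(x$individuals$ht_status))) {
    ht <- table(x$individuals$ht_status)
    cat("  baseline status:",
        paste(sprintf("%s %d", names(ht), as.integer(ht)), collapse = ", "),
        "\n")
  }
  invisible(x)
}
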