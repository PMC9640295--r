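# Full study replica: eligibility screen -> baseline table -> CoV tables ->
# BPV regression -> adaptation -> dipping -> reference ranges. Each stage
# tolerates an insufficient-data failure (recorded in the manifest) so one
# sparse table never aborts the rest, mirroring analyses whose per-stage
# sample sizes legitimately differ.

# Long vector of (value, individual_id) pairs for one parameter, honouring
# session validity flags; PWV comes from the per-visit columns.
param_values <- function(cohort, parameter, group = "all", study = "ALL") {
  ind <- cohort$individuals
  keep_ids <- ind$individual_id
  if (group != "all") keep_ids <- keep_ids[!is.na(ind$ht_status) &
                                             ind$ht_status == group]
  if (study != "ALL") keep_ids <- intersect(keep_ids,
                                            ind$individual_id[ind$study == study])
  if (parameter == "pwv") {
    cols <- grep("^pwv_v", names(ind), value = TRUE)
    long <- do.call(rbind, lapply(cols, function(cl) {
      data.frame(individual_id = ind$individual_id, value = ind[[cl]])
    }))
  } else {
    s <- cohort$sessions
    if ("ok" %in% names(s)) s <- s[s$ok %in% TRUE, ]
    long <- data.frame(individual_id = s$individual_id, value = s[[parameter]])
  }
  long <- long[!is.na(long$value) & long$individual_id %in% keep_ids, ]
  long
}

ratings_matrix <- function(sessions, column, n_required) {
  counts <- table(sessions$individual_id)
  keep <- names(counts)[counts == n_required]
  s <- sessions[sessions$individual_id %in% keep, ]
  mat <- matrix(NA_character_, length(keep), n_required,
                dimnames = list(keep, NULL))
  mat[cbind(match(s$individual_id, keep), s$session_index)] <- s[[column]]
  mat
}

#' Run the full reproducibility analysis on a cohort
#'
#' Executes every stage of the sequential-ABPM reproducibility pipeline on
#' an [abpm_cohort][read_cohort()] (simulated or loaded): arm stability
#' screening, a baseline characteristics table, within-individual CoV
#' tables by parameter, hypertensive status and study, BPV determinant
#' regressions, the device-adaptation test, nocturnal-dipping prevalence,
#' stability and Fleiss-kappa agreement, and illustrative 95% reading
#' ranges. Stages that fail for lack of data are skipped and recorded in
#' the manifest.
#'
#' @param cohort an `abpm_cohort` with a sessions table.
#' @param config an [analysis_config()].
#' @return object of class `abpm_report`: named list of tables plus a
#'   `manifest` (seed, stage ns, dropped-case ledger, stage errors).
#' @export
run_full_analysis <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(cohort, "abpm_cohort"))
  if (is.null(cohort$sessions)) {
    stop("cohort has no sessions table; run summarize_cohort() first",
         call. = FALSE)
  }
  manifest <- list(seed = cohort$seed,
                   n_individuals = nrow(cohort$individuals),
                   n_sessions = nrow(cohort$sessions),
                   errors = list(), dropped = list())
  tables <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  ind <- cohort$individuals
  sessions <- cohort$sessions
  bp_params <- c("sbp_day", "sbp_night", "dbp_day", "dbp_night")
  all_params <- c("sbp_day", "sbp_night", "sbp_24h", "dbp_day", "dbp_night",
                  "dbp_24h", "hr_day", "hr_night", "hr_24h", "pwv")

  # -- arm eligibility screen ------------------------------------------------
  tables$eligibility <- run_stage("eligibility", {
    rows <- list()
    for (st in unique(ind$study)) {
      for (arm in unique(ind$arm[ind$study == st])) {
        ids <- ind$individual_id[ind$study == st & ind$arm == arm]
        s <- sessions[sessions$individual_id %in% ids, ]
        n_req <- max(s$session_index)
        for (p in bp_params) {
          mat <- ratings_matrix_numeric(s, p, n_req)
          dec <- tryCatch(screen_arm_eligibility(mat, config$bonferroni),
                          error = function(e) NULL)
          if (is.null(dec)) next
          rows[[length(rows) + 1L]] <- data.frame(
            study = st, arm = arm, parameter = p,
            anova_p = dec$anova_p, posthoc_p = dec$posthoc_p,
            eligible = dec$eligible, reason = dec$reason)
        }
      }
    }
    do.call(rbind, rows)
  })

  # -- baseline characteristics ---------------------------------------------
  tables$baseline <- run_stage("baseline", {
    baseline_table(cohort)
  })

  # -- CoV table -------------------------------------------------------------
  tables$cov <- run_stage("cov", {
    groups <- c("all", "normotensive", "hypertensive")
    studies <- c(unique(ind$study), "ALL")
    rows <- list()
    for (g in groups) for (st in studies) for (p in all_params) {
      long <- param_values(cohort, p, g, st)
      cw <- tryCatch(
        cov_within(long$value, long$individual_id, config$coverage,
                   config$ci_method, parameter = p, group = g),
        error = function(e) NULL)
      if (is.null(cw)) next
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, group = g, study = st,
        n_individuals = cw$n_individuals, df = cw$df,
        cov_pct = cw$cov_pct, ci_lo = cw$ci_lo, ci_hi = cw$ci_hi,
        rendered = fmt_cov_ci(cw$cov_pct, cw$ci_lo, cw$ci_hi))
    }
    do.call(rbind, rows)
  })

  # -- group comparisons (normotensive vs hypertensive, pooled) -------------
  tables$cov_comparison <- run_stage("cov_comparison", {
    rows <- lapply(all_params, function(p) {
      a <- param_values(cohort, p, "normotensive", "ALL")
      b <- param_values(cohort, p, "hypertensive", "ALL")
      cmp <- tryCatch(compare_cov(
        cov_within(a$value, a$individual_id, config$coverage,
                   config$ci_method, p, "normotensive"),
        cov_within(b$value, b$individual_id, config$coverage,
                   config$ci_method, p, "hypertensive")),
        error = function(e) NULL)
      if (is.null(cmp)) return(NULL)
      data.frame(parameter = p, cov_normotensive = cmp$cov_a,
                 cov_hypertensive = cmp$cov_b,
                 ci_overlap = cmp$ci_overlap, z = cmp$z, p = cmp$p)
    })
    do.call(rbind, rows)
  })

  # -- BPV regression --------------------------------------------------------
  tables$bpv_regression <- run_stage("bpv_regression", {
    fits <- bpv_regression(cohort)
    do.call(rbind, lapply(names(fits), function(nm) {
      cbind(outcome = nm, fits[[nm]]$coefficients,
            n = fits[[nm]]$n, r_squared = fits[[nm]]$r_squared)
    }))
  })

  # -- adaptation ------------------------------------------------------------
  tables$adaptation <- run_stage("adaptation", {
    n_req <- max(table(sessions$individual_id))
    do.call(rbind, lapply(bp_params, function(p) {
      a <- adaptation_test(sessions, p, n_req)
      data.frame(parameter = p, n_subjects = a$n_subjects,
                 F = a$F, df_num = a$df_num, df_den = a$df_den, p = a$p,
                 t(stats::setNames(a$means,
                                   paste0("mean_s", seq_along(a$means)))))
    }))
  })

  # -- dipping ---------------------------------------------------------------
  tables$dipping <- run_stage("dipping", {
    base <- sessions[sessions$session_index == 1L & !is.na(sessions$dip_binary), ]
    prev <- list(
      binary = table(factor(base$dip_binary, c("dipper", "nondipper"))),
      category = table(factor(base$dip_category,
                              c("reverse", "reduced", "normal", "extreme"))))
    stab <- dip_stability(sessions, ind)
    n_req <- max(table(sessions$individual_id))
    kappas <- list()
    for (g in c("normotensive", "hypertensive")) {
      ids <- ind$individual_id[ind$ht_status %in% g]
      s <- sessions[sessions$individual_id %in% ids, ]
      for (col in c("dip_binary", "dip_category")) {
        kp <- tryCatch(fleiss_kappa(ratings_matrix(s, col, n_req)),
                       error = function(e) NULL)
        if (!is.null(kp)) {
          kappas[[paste(g, col, sep = ".")]] <- data.frame(
            group = g, scheme = col, kappa = kp$kappa, z = kp$z, p = kp$p,
            n_subjects = kp$n_subjects, n_raters = kp$n_raters)
        }
      }
    }
    list(prevalence = prev, stability = stab,
         kappa = do.call(rbind, c(kappas, list(make.row.names = FALSE))))
  })

  # -- reference ranges ------------------------------------------------------
  tables$ranges <- run_stage("ranges", {
    do.call(rbind, lapply(names(config$range_means), function(p) {
      cw_row <- tables$cov[tables$cov$parameter == p &
                             tables$cov$group == "all" &
                             tables$cov$study == "ALL", ]
      if (nrow(cw_row) == 0) return(NULL)
      rr <- reference_range(config$range_means[[p]], cw_row$cov_pct,
                            config$coverage)
      data.frame(parameter = p, true_mean = rr$true_mean,
                 cov_pct = rr$cov_pct, lo = rr$lo, hi = rr$hi,
                 presented = rr$presented)
    }))
  })

  structure(list(tables = tables, manifest = manifest, config = config),
            class = "abpm_report")
}

# numeric analogue of ratings_matrix for screen/adaptation stages
ratings_matrix_numeric <- function(sessions, column, n_required) {
  counts <- table(sessions$individual_id)
  keep <- names(counts)[counts == n_required]
  s <- sessions[sessions$individual_id %in% keep, ]
  mat <- matrix(NA_real_, length(keep), n_required,
                dimnames = list(keep, NULL))
  mat[cbind(match(s$individual_id, keep), s$session_index)] <- s[[column]]
  mat
}

baseline_table <- function(cohort) {
  ind <- cohort$individuals
  base <- cohort$sessions[cohort$sessions$session_index == 1L, ]
  bs <- base[match(ind$individual_id, base$individual_id), ]
  studies <- c(unique(ind$study), "ALL")
  rows <- list()
  add <- function(study, characteristic, mean = NA, sd = NA, n = NA,
                  pct = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      study = study, characteristic = characteristic,
      mean = mean, sd = sd, n = n, pct = pct)
  }
  for (st in studies) {
    sel <- if (st == "ALL") rep(TRUE, nrow(ind)) else ind$study == st
    add(st, "n", n = sum(sel))
    for (v in c("age", "bmi")) {
      add(st, v, mean(ind[[v]][sel]), stats::sd(ind[[v]][sel]))
    }
    add(st, "pwv", mean(ind$pwv_v1[sel], na.rm = TRUE),
        stats::sd(ind$pwv_v1[sel], na.rm = TRUE))
    add(st, "female", n = sum(ind$sex[sel] == "female"),
        pct = 100 * mean(ind$sex[sel] == "female"))
    add(st, "white", n = sum(ind$ethnicity_white[sel]),
        pct = 100 * mean(ind$ethnicity_white[sel]))
    add(st, "antihypertensive", n = sum(ind$antihypertensive[sel]),
        pct = 100 * mean(ind$antihypertensive[sel]))
    for (v in c("clinic_sbp", "clinic_dbp", "clinic_hr")) {
      add(st, v, mean(ind[[v]][sel], na.rm = TRUE),
          stats::sd(ind[[v]][sel], na.rm = TRUE))
    }
    for (v in c("sbp_day", "sbp_night", "sbp_24h", "dbp_day", "dbp_night",
                "dbp_24h", "hr_day", "hr_night", "hr_24h")) {
      add(st, v, mean(bs[[v]][sel], na.rm = TRUE),
          stats::sd(bs[[v]][sel], na.rm = TRUE))
    }
  }
  do.call(rbind, rows)
}

#' @export
print.abpm_report <- function(x, ...) {
  cat("ABPM reproducibility report\n")
  m <- x$manifest
  cat(sprintf("  cohort: %d individuals, %d sessions (seed %s)\n",
              m$n_individuals, m$n_sessions,
              if (is.null(m$seed)) "external data" else m$seed))
  cv <- x$tables$cov
  if (!is.null(cv)) {
    pooled <- cv[cv$group == "all" & cv$study == "ALL", ]
    cat("  within-individual CoV (all individuals, pooled):\n")
    for (i in seq_len(nrow(pooled))) {
      cat(sprintf("    %-10s %s%%\n", pooled$parameter[i], pooled$rendered[i]))
    }
  }
  if (!is.null(x$tables$ranges)) {
    for (i in seq_len(nrow(x$tables$ranges))) {
      r <- x$tables$ranges[i, ]
      cat(sprintf("  95%% reading range, %s true mean %g mmHg: %s mmHg\n",
                  r$parameter, r$true_mean, r$presented))
    }
  }
  if (length(m$errors)) {
    cat("  skipped stages:", paste(names(m$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' One CSV per report table (deterministic column order; CoV values
#' rendered to one decimal with the CI as "(lo–hi)") plus a JSON manifest.
#' Tables a stage could not produce are written as header-only files.
#'
#' @param report an `abpm_report` from [run_full_analysis()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_results <- function(report, out_dir) {
  stopifnot(inherits(report, "abpm_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  headers <- list(
    table1_baseline = c("study", "characteristic", "mean", "sd", "n", "pct"),
    table2_cov = c("parameter", "group", "study", "n_individuals", "df",
                   "cov_pct", "ci_lo", "ci_hi", "rendered"),
    table2_cov_comparison = c("parameter", "cov_normotensive",
                              "cov_hypertensive", "ci_overlap", "z", "p"),
    table3_bpv_regression = c("outcome", "term", "b", "beta", "se", "p",
                              "n", "r_squared"),
    eligibility = c("study", "arm", "parameter", "anova_p", "posthoc_p",
                    "eligible", "reason"),
    adaptation = c("parameter", "n_subjects", "F", "df_num", "df_den", "p"),
    ranges = c("parameter", "true_mean", "cov_pct", "lo", "hi", "presented")
  )
  src <- list(table1_baseline = report$tables$baseline,
              table2_cov = report$tables$cov,
              table2_cov_comparison = report$tables$cov_comparison,
              table3_bpv_regression = report$tables$bpv_regression,
              eligibility = report$tables$eligibility,
              adaptation = report$tables$adaptation,
              ranges = report$tables$ranges)
  paths <- character(0)
  for (nm in names(headers)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    df <- src[[nm]]
    if (is.null(df) || nrow(df) == 0) {
      df <- as.data.frame(stats::setNames(
        rep(list(character(0)), length(headers[[nm]])), headers[[nm]]))
    }
    utils::write.csv(df, p, row.names = FALSE, na = "")
    paths <- c(paths, p)
  }
  dip <- report$tables$dipping
  p <- file.path(out_dir, "dipping.csv")
  if (!is.null(dip)) {
    prev_b <- dip$prevalence$binary
    prev_c <- dip$prevalence$category
    st <- dip$stability$overall
    rows <- rbind(
      data.frame(section = "baseline_prevalence",
                 item = c(names(prev_b), names(prev_c)),
                 value = c(as.numeric(prev_b), as.numeric(prev_c))),
      data.frame(section = "stability",
                 item = c(names(st$binary), names(st$category)),
                 value = round(c(as.numeric(st$binary),
                                 as.numeric(st$category)), 4)))
    if (!is.null(dip$kappa) && nrow(dip$kappa)) {
      rows <- rbind(rows, data.frame(
        section = "fleiss_kappa",
        item = paste(dip$kappa$group, dip$kappa$scheme, sep = "."),
        value = round(dip$kappa$kappa, 4)))
    }
    utils::write.csv(rows, p, row.names = FALSE)
  } else {
    utils::write.csv(data.frame(section = character(0), item = character(0),
                                value = numeric(0)), p, row.names = FALSE)
  }
  paths <- c(paths, p)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(report$manifest, mp, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(c(paths, mp))
}
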