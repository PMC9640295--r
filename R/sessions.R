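#' Classify nocturnal dipping
#'
#' Percent fall of the night-time systolic mean relative to the daytime
#' systolic mean, `dip_pct = 100 * (sbp_day - sbp_night) / sbp_day`, mapped
#' to the four classic dipping patterns and the dichotomous
#' dipper/nondipper outcome.
#'
#' Boundary conventions (made explicit because the clinical literature is
#' not internally consistent about them): a dip of exactly 0% is `reduced`;
#' exactly 10% is `normal` and counts as a dipper (the binary rule is a fall
#' of at least 10%); exactly 20% is `normal`. So the four-level partition is
#' `reverse` (< 0), `reduced` [0, 10), `normal` [10, 20], `extreme` (> 20),
#' and the binary outcome is the deterministic collapse
#' \{normal, extreme\} -> dipper, \{reduced, reverse\} -> nondipper.
#'
#' @param sbp_day daytime systolic mean, mmHg (> 0).
#' @param sbp_night night-time systolic mean, mmHg. Both may be vectors.
#' @return data frame with `dip_pct`, `dip_binary` ("dipper"/"nondipper"),
#'   `dip_category` ("reverse"/"reduced"/"normal"/"extreme").
#' @examples
#' classify_dipping(130, 110)
#' classify_dipping(c(120, 110, 150), c(120, 115, 115))
#' @export
classify_dipping <- function(sbp_day, sbp_night) {
  stopifnot(length(sbp_day) == length(sbp_night))
  if (any(!is.na(sbp_day) & sbp_day <= 0)) {
    stop("sbp_day must be positive", call. = FALSE)
  }
  dip_pct <- 100 * (sbp_day - sbp_night) / sbp_day
  dip_category <- ifelse(dip_pct < 0, "reverse",
                  ifelse(dip_pct < 10, "reduced",
                  ifelse(dip_pct <= 20, "normal", "extreme")))
  dip_binary <- ifelse(dip_category %in% c("normal", "extreme"),
                       "dipper", "nondipper")
  dip_binary[is.na(dip_pct)] <- NA_character_
  data.frame(dip_pct = dip_pct, dip_binary = dip_binary,
             dip_category = dip_category)
}

#' Summarize one ABPM session from raw readings and the sleep diary
#'
#' Splits a session's cuff readings into diary-defined day and night
#' periods and forms the session-level means the downstream reproducibility
#' analyses consume. Night readings are those with timestamps in the
#' half-open sleep interval `[sleep_onset, wake_time)` — a reading taken
#' exactly at wake time counts as day — and all windowing is done on
#' absolute datetimes, so sessions crossing midnight need no special
#' handling. Day and night means are unweighted arithmetic means of valid
#' readings; the 24-h mean is the unweighted mean of all valid readings
#' pooled (the device cadence, denser by day, already down-weights the
#' night). A reading is valid when it falls inside the [validity_rules()]
#' bounds (and, by default, has SBP > DBP). Sessions with fewer valid
#' readings than the rules require in either period are returned but
#' flagged (`ok = FALSE`); periods with no valid readings get `NA` means.
#'
#' @param readings data frame with `timestamp` (POSIXct), `sbp`, `dbp`,
#'   `hr` for one session.
#' @param diary_entry list or one-row data frame with `sleep_onset` and
#'   `wake_time` (POSIXct). Required: there is no clock-time fallback.
#' @param rules a [validity_rules()] object.
#' @return one-row data frame in the `sessions.csv` schema (day/night/24-h
#'   means for SBP, DBP, HR; valid counts `n_day`, `n_night`; `dip_pct`,
#'   `dip_binary`, `dip_category`; logical `ok`).
#' @export
summarize_session <- function(readings, diary_entry, rules = validity_rules()) {
  stopifnot(inherits(rules, "validity_rules"))
  if (nrow(readings) < 1L) stop("no readings supplied", call. = FALSE)
  if (is.null(diary_entry) ||
      is.null(diary_entry$sleep_onset) || is.null(diary_entry$wake_time) ||
      is.na(diary_entry$sleep_onset) || is.na(diary_entry$wake_time)) {
    stop("missing diary entry: day/night windows require sleep_onset and wake_time",
         call. = FALSE)
  }
  onset <- as.POSIXct(diary_entry$sleep_onset)
  wake <- as.POSIXct(diary_entry$wake_time)
  if (!(onset < wake)) stop("sleep_onset must precede wake_time", call. = FALSE)
  ts <- as.POSIXct(readings$timestamp)

  valid <- !is.na(readings$sbp) & !is.na(readings$dbp) & !is.na(readings$hr) &
    readings$sbp >= rules$sbp_bounds[1] & readings$sbp <= rules$sbp_bounds[2] &
    readings$dbp >= rules$dbp_bounds[1] & readings$dbp <= rules$dbp_bounds[2] &
    readings$hr >= rules$hr_bounds[1] & readings$hr <= rules$hr_bounds[2]
  if (rules$require_sbp_gt_dbp) valid <- valid & readings$sbp > readings$dbp

  night <- ts >= onset & ts < wake
  vday <- valid & !night
  vnight <- valid & night

  mean_or_na <- function(v, sel) if (any(sel)) mean(v[sel]) else NA_real_
  sbp_day <- mean_or_na(readings$sbp, vday)
  sbp_night <- mean_or_na(readings$sbp, vnight)
  dip <- if (!is.na(sbp_day) && !is.na(sbp_night)) {
    classify_dipping(sbp_day, sbp_night)
  } else {
    data.frame(dip_pct = NA_real_, dip_binary = NA_character_,
               dip_category = NA_character_)
  }
  n_day <- sum(vday); n_night <- sum(vnight)
  data.frame(
    sbp_day = sbp_day, sbp_night = sbp_night,
    sbp_24h = mean_or_na(readings$sbp, valid),
    dbp_day = mean_or_na(readings$dbp, vday),
    dbp_night = mean_or_na(readings$dbp, vnight),
    dbp_24h = mean_or_na(readings$dbp, valid),
    hr_day = mean_or_na(readings$hr, vday),
    hr_night = mean_or_na(readings$hr, vnight),
    hr_24h = mean_or_na(readings$hr, valid),
    n_day = n_day, n_night = n_night,
    dip_pct = dip$dip_pct, dip_binary = dip$dip_binary,
    dip_category = dip$dip_category,
    ok = n_day >= rules$min_day & n_night >= rules$min_night
  )
}

#' Summarize every session of a readings + diary file pair
#'
#' Applies [summarize_session()] per (individual, session) group, ordering
#' each individual's sessions by first reading time to assign
#' `session_index`. Sessions without a diary entry raise an error naming
#' the session.
#'
#' @param readings data frame in the `readings.csv` schema.
#' @param diary data frame in the `diary.csv` schema.
#' @param rules a [validity_rules()] object.
#' @return data frame in the `sessions.csv` schema, one row per session.
#' @export
summarize_sessions <- function(readings, diary, rules = validity_rules()) {
  stopifnot(all(c("individual_id", "session_id", "timestamp",
                  "sbp", "dbp", "hr") %in% names(readings)))
  key <- paste(readings$individual_id, readings$session_id, sep = "\r")
  dkey <- paste(diary$individual_id, diary$session_id, sep = "\r")
  if (anyDuplicated(dkey))
    stop("duplicate diary entry for a session", call. = FALSE)
  groups <- split(seq_len(nrow(readings)), key)
  rows <- lapply(names(groups), function(k) {
    idx <- groups[[k]]
    di <- match(k, dkey)
    if (is.na(di)) {
      ids <- strsplit(k, "\r", fixed = TRUE)[[1]]
      stop("missing diary entry for individual ", ids[1],
           " session ", ids[2], call. = FALSE)
    }
    s <- summarize_session(readings[idx, , drop = FALSE],
                           diary[di, , drop = FALSE], rules)
    cbind(data.frame(individual_id = readings$individual_id[idx[1]],
                     session_id = readings$session_id[idx[1]],
                     start = min(as.POSIXct(readings$timestamp[idx]))),
          s)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$individual_id, out$start), , drop = FALSE]
  out$session_index <- stats::ave(seq_len(nrow(out)), out$individual_id,
                                  FUN = seq_along)
  out$start <- NULL
  rownames(out) <- NULL
  out[c("individual_id", "session_id", "session_index",
        setdiff(names(out), c("individual_id", "session_id", "session_index")))]
}

#' Stability of dipping classification across repeated sessions
#'
#' Labels each individual with at least two classified sessions as
#' `always-dipper`, `never-dipper` or `changeable` from the binary
#' dipper/nondipper sequence, and as `kept-baseline-category` or
#' `changed-category` according to whether every session's four-level
#' dipping category equals the baseline session's. When an `individuals`
#' table with `ht_status` is supplied, cohort tabulations are stratified by
#' baseline hypertensive status.
#'
#' @param sessions session-level data frame with `individual_id`,
#'   `session_index`, `dip_binary`, `dip_category`.
#' @param individuals optional data frame with `individual_id`, `ht_status`.
#' @return object of class `dip_stability`: per-individual labels plus
#'   tabulations (proportions) overall and, if available, by `ht_status`.
#' @export
dip_stability <- function(sessions, individuals = NULL) {
  need <- c("individual_id", "session_index", "dip_binary", "dip_category")
  stopifnot(all(need %in% names(sessions)))
  s <- sessions[!is.na(sessions$dip_binary), need]
  sp <- split(s[order(s$session_index), ], s$individual_id[order(s$session_index)])
  n_dropped <- sum(vapply(sp, nrow, 1L) < 2L)
  sp <- sp[vapply(sp, nrow, 1L) >= 2L]
  if (!length(sp)) stop("no individual has >= 2 classified sessions", call. = FALSE)
  if (n_dropped > 0)
    message(n_dropped, " individual(s) with < 2 classified sessions excluded")
  labels <- do.call(rbind, lapply(sp, function(d) {
    bin <- d$dip_binary
    data.frame(
      individual_id = d$individual_id[1],
      n_sessions = nrow(d),
      binary_label = if (all(bin == "dipper")) "always-dipper"
                     else if (all(bin == "nondipper")) "never-dipper"
                     else "changeable",
      category_label = if (all(d$dip_category == d$dip_category[1]))
        "kept-baseline-category" else "changed-category",
      row.names = NULL
    )
  }))
  rownames(labels) <- NULL
  tab <- function(d) {
    list(binary = prop.table(table(factor(d$binary_label,
           c("always-dipper", "never-dipper", "changeable")))),
         category = prop.table(table(factor(d$category_label,
           c("kept-baseline-category", "changed-category")))))
  }
  by_status <- NULL
  if (!is.null(individuals) && "ht_status" %in% names(individuals)) {
    st <- individuals$ht_status[match(labels$individual_id,
                                      individuals$individual_id)]
    by_status <- lapply(split(labels, st), tab)
  }
  structure(list(labels = labels, overall = tab(labels),
                 by_status = by_status, n_dropped = n_dropped),
            class = "dip_stability")
}

#' @export
print.dip_stability <- function(x, ...) {
  cat(sprintf("Dipping stability over repeated sessions (%d individuals)\n",
              nrow(x$labels)))
  b <- x$overall$binary; ct <- x$overall$category
  cat(sprintf("  binary: %.0f%% always-dipper, %.0f%% never-dipper, %.0f%% changeable\n",
              100 * b[["always-dipper"]], 100 * b[["never-dipper"]],
              100 * b[["changeable"]]))
  cat(sprintf("  four-level: %.0f%% kept baseline category, %.0f%% changed\n",
              100 * ct[["kept-baseline-category"]],
              100 * ct[["changed-category"]]))
  if (!is.null(x$by_status)) {
    for (g in names(x$by_status)) {
      cat(sprintf("  [%s] changeable %.0f%%, changed category %.0f%%\n", g,
                  100 * x$by_status[[g]]$binary[["changeable"]],
                  100 * x$by_status[[g]]$category[["changed-category"]]))
    }
  }
  invisible(x)
}
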