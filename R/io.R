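# CSV schemas shared by the simulator, the summarizer and the analyses.

SCHEMA <- list(
  individuals = c("individual_id", "study", "arm", "age", "sex", "ethnicity",
                  "bmi", "antihypertensive", "clinic_sbp", "clinic_dbp",
                  "clinic_hr"),
  sessions = c("individual_id", "session_id", "session_index",
               "sbp_day", "sbp_night", "sbp_24h", "dbp_day", "dbp_night",
               "dbp_24h", "hr_day", "hr_night", "hr_24h",
               "n_day", "n_night", "dip_pct", "dip_binary", "dip_category"),
  readings = c("individual_id", "session_id", "timestamp", "sbp", "dbp", "hr"),
  diary = c("individual_id", "session_id", "sleep_onset", "wake_time")
)

parse_dt <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  as.POSIXct(x, tz = "UTC",
             tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
}

format_dt <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

check_schema <- function(df, what) {
  missing_cols <- setdiff(SCHEMA[[what]], names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s file is missing mandatory column(s): %s", what,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

check_referential <- function(ids, known, what) {
  unknown <- setdiff(unique(ids), known)
  if (length(unknown)) {
    stop(sprintf("%s file references unknown individual_id(s): %s", what,
                 paste(utils::head(unknown, 5), collapse = ", ")),
         call. = FALSE)
  }
}

#' Derive baseline hypertensive status
#'
#' An individual is hypertensive when the daytime systolic mean of their
#' baseline (first) session is at or above the threshold; exactly at the
#' threshold counts as hypertensive. Individuals without a baseline daytime
#' mean get `NA`.
#'
#' @param individuals individuals data frame.
#' @param sessions sessions data frame with `session_index` and `sbp_day`.
#' @param threshold mmHg, default 135.
#' @return character vector parallel to `individuals` rows, values
#'   `"normotensive"` / `"hypertensive"` / `NA`.
#' @export
derive_ht_status <- function(individuals, sessions, threshold = 135) {
  base <- sessions[sessions$session_index == 1L, c("individual_id", "sbp_day")]
  sbp <- base$sbp_day[match(individuals$individual_id, base$individual_id)]
  ifelse(is.na(sbp), NA_character_,
         ifelse(sbp >= threshold, "hypertensive", "normotensive"))
}

#' Read a cohort from CSV files
#'
#' Loads an individuals table plus either pre-summarized sessions or raw
#' readings with their sleep diary (summarization is then deferred to
#' [summarize_cohort()]). Mandatory columns are checked by name, extra
#' columns are preserved, every session/reading must reference a known
#' individual, and duplicate (individual, session) keys are an error.
#' Baseline hypertensive status is derived from the sessions table when one
#' is available.
#'
#' @param individuals_path path to `individuals.csv`.
#' @param sessions_path optional path to `sessions.csv`.
#' @param readings_path,diary_path optional paths to `readings.csv` and
#'   `diary.csv` (both required together).
#' @param config an [analysis_config()] (supplies the hypertension
#'   threshold).
#' @return an `abpm_cohort` object.
#' @export
read_cohort <- function(individuals_path, sessions_path = NULL,
                        readings_path = NULL, diary_path = NULL,
                        config = analysis_config()) {
  individuals <- utils::read.csv(individuals_path, stringsAsFactors = FALSE)
  check_schema(individuals, "individuals")
  if (anyDuplicated(individuals$individual_id)) {
    stop("duplicate individual_id in individuals file", call. = FALSE)
  }
  if (is.logical(individuals$antihypertensive) ||
      is.character(individuals$antihypertensive)) {
    individuals$antihypertensive <- as.logical(individuals$antihypertensive)
  }
  if (!"ethnicity_white" %in% names(individuals)) {
    individuals$ethnicity_white <- individuals$ethnicity == "white"
  }
  known <- individuals$individual_id

  sessions <- readings <- diary <- NULL
  if (!is.null(sessions_path)) {
    sessions <- utils::read.csv(sessions_path, stringsAsFactors = FALSE)
    check_schema(sessions, "sessions")
    check_referential(sessions$individual_id, known, "sessions")
    if (anyDuplicated(paste(sessions$individual_id, sessions$session_id))) {
      stop("duplicate (individual_id, session_id) key in sessions file",
           call. = FALSE)
    }
  }
  if (!is.null(readings_path) || !is.null(diary_path)) {
    if (is.null(readings_path) || is.null(diary_path)) {
      stop("readings and diary files must be supplied together", call. = FALSE)
    }
    readings <- utils::read.csv(readings_path, stringsAsFactors = FALSE)
    check_schema(readings, "readings")
    check_referential(readings$individual_id, known, "readings")
    readings$timestamp <- parse_dt(readings$timestamp)
    diary <- utils::read.csv(diary_path, stringsAsFactors = FALSE)
    check_schema(diary, "diary")
    check_referential(diary$individual_id, known, "diary")
    if (anyDuplicated(paste(diary$individual_id, diary$session_id))) {
      stop("duplicate (individual_id, session_id) key in diary file",
           call. = FALSE)
    }
    diary$sleep_onset <- parse_dt(diary$sleep_onset)
    diary$wake_time <- parse_dt(diary$wake_time)
  }
  if (is.null(sessions) && is.null(readings)) {
    stop("supply either a sessions file or readings + diary files",
         call. = FALSE)
  }
  if (!is.null(sessions)) {
    individuals$ht_status <- derive_ht_status(individuals, sessions,
                                              config$ht_threshold)
  } else if (!"ht_status" %in% names(individuals)) {
    individuals$ht_status <- NA_character_
  }
  structure(list(individuals = individuals, sessions = sessions,
                 readings = readings, diary = diary,
                 truth = NULL, spec = NULL, seed = NULL),
            class = "abpm_cohort")
}

#' Summarize a cohort's raw readings into its sessions table
#'
#' Runs [summarize_sessions()] on the cohort's readings and diary, stores
#' the result as the cohort's sessions table and re-derives baseline
#' hypertensive status.
#'
#' @param cohort an `abpm_cohort` holding readings and diary.
#' @param rules a [validity_rules()] object.
#' @param ht_threshold hypertension threshold in mmHg.
#' @return the cohort with `sessions` populated.
#' @export
summarize_cohort <- function(cohort, rules = validity_rules(),
                             ht_threshold = 135) {
  stopifnot(inherits(cohort, "abpm_cohort"))
  if (is.null(cohort$readings) || is.null(cohort$diary)) {
    stop("cohort holds no readings/diary to summarize", call. = FALSE)
  }
  cohort$sessions <- summarize_sessions(cohort$readings, cohort$diary, rules)
  cohort$individuals$ht_status <- derive_ht_status(cohort$individuals,
                                                   cohort$sessions,
                                                   ht_threshold)
  cohort
}

#' Write a cohort to CSV files
#'
#' Emits `individuals.csv` and whichever of `sessions.csv`, `readings.csv`,
#' `diary.csv` the cohort holds, with ISO-8601 timestamps, so that
#' [read_cohort()] round-trips every typed field.
#'
#' @param cohort an `abpm_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "abpm_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE, na = "")
    paths <<- c(paths, p)
  }
  wr(cohort$individuals, "individuals.csv")
  if (!is.null(cohort$sessions)) wr(cohort$sessions, "sessions.csv")
  if (!is.null(cohort$readings)) {
    r <- cohort$readings
    r$timestamp <- format_dt(r$timestamp)
    wr(r, "readings.csv")
  }
  if (!is.null(cohort$diary)) {
    d <- cohort$diary
    d$sleep_onset <- format_dt(d$sleep_onset)
    d$wake_time <- format_dt(d$wake_time)
    wr(d, "diary.csv")
  }
  invisible(paths)
}
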