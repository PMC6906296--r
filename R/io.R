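# On-disk formats: sensor time-series CSV, session-annotation JSON,
# clinical-score table, PVT reaction-time log.
#
# Sensor CSV dialect: comma-separated, UTF-8, '.' decimal, one header line,
# preceded by '#'-prefixed metadata lines carrying subject, body location
# and nominal sample rate. Time is seconds since recording start on the
# device clock; annotations share that clock. Missing samples are encoded
# by timestamp gaps (never sentinel values); a gap of more than two nominal
# sample periods splits a contiguous segment.

BODY_LOCATIONS <- c("chest", "left_ankle", "right_ankle", "left_wrist",
                    "right_wrist", "left_thigh", "right_thigh", "lumbar")

ANNOTATION_LABELS <- c("stand", "balance_30s", "sit", "tug", "walk_2min",
                       "pvt", "sleep", "other")

EDSS_GRID <- seq(0, 10, by = 0.5)

#' Construct a sensor recording
#'
#' Bundles a uniformly sampled tri-axial accelerometer + gyroscope stream
#' from one device at one body location, with optional inter-beat intervals,
#' into a validated `ms_recording` tibble. Acceleration is in m/s^2,
#' angular velocity in deg/s, time in seconds since recording start.
#'
#' @param data tibble with columns `t`, `ax`, `ay`, `az`, `gx`, `gy`, `gz`
#'   (and optionally `ibi_ms`, `NA` except at beat times).
#' @param subject_id subject identifier.
#' @param body_location one of chest, left/right ankle, wrist or thigh,
#'   lumbar ("sternum" is accepted as an alias for chest).
#' @param sample_rate_hz nominal sample rate, Hz (> 0).
#' @return an `ms_recording` tibble with metadata attributes.
#' @export
sensor_recording <- function(data, subject_id, body_location, sample_rate_hz) {
  if (identical(body_location, "sternum")) body_location <- "chest"
  if (!body_location %in% BODY_LOCATIONS) {
    validation_error(sprintf("unknown body location '%s'", body_location))
  }
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 ||
      sample_rate_hz <= 0) {
    validation_error("sample_rate_hz must be a positive scalar")
  }
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    format_error(sprintf("missing sensor column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)
  if (nrow(data) > 1 && any(diff(data$t) <= 0)) {
    validation_error("non-monotone timestamps in sensor stream")
  }
  out <- data
  attr(out, "subject_id") <- as.character(subject_id)
  attr(out, "body_location") <- body_location
  attr(out, "sample_rate_hz") <- sample_rate_hz
  class(out) <- c("ms_recording", class(tibble::tibble()))
  out
}

#' @export
print.ms_recording <- function(x, ...) {
  cat(sprintf("<ms_recording> subject %s, %s, %g Hz, %d samples, %.1f s\n",
              attr(x, "subject_id"), attr(x, "body_location"),
              attr(x, "sample_rate_hz"), nrow(x),
              if (nrow(x)) diff(range(x$t)) else 0))
  NextMethod()
}

rec_meta <- function(rec) {
  list(subject_id = attr(rec, "subject_id"),
       body_location = attr(rec, "body_location"),
       sample_rate_hz = attr(rec, "sample_rate_hz"))
}

#' Split a recording into contiguous segments
#'
#' A timestamp gap larger than `gap_periods` nominal sample periods starts
#' a new segment.
#'
#' @param rec an `ms_recording`.
#' @param gap_periods gap threshold in sample periods (default 2).
#' @return the recording tibble with an integer `segment` column.
#' @export
contiguous_segments <- function(rec, gap_periods = 2) {
  dt <- 1 / attr(rec, "sample_rate_hz")
  brk <- c(FALSE, diff(rec$t) > gap_periods * dt)
  out <- rec
  out$segment <- cumsum(brk) + 1L
  out
}

#' Read a sensor time-series CSV
#'
#' @param path path to a sensor CSV written by [write_sensor_csv()] (or any
#'   file in the documented dialect).
#' @return a validated [sensor_recording()].
#' @export
read_sensor_csv <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  hdr <- readLines(path, n = 20L)
  meta_lines <- grep("^#", hdr, value = TRUE)
  get_meta <- function(key) {
    m <- grep(sprintf("^#\\s*%s\\s*:", key), meta_lines, value = TRUE)
    if (length(m) == 0) format_error(sprintf("missing '# %s:' metadata", key))
    trimws(sub(sprintf("^#\\s*%s\\s*:", key), "", m[1]))
  }
  subject <- get_meta("subject")
  location <- get_meta("location")
  rate <- suppressWarnings(as.numeric(get_meta("sample_rate_hz")))
  if (is.na(rate)) format_error("sample_rate_hz metadata is not numeric")
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  sensor_recording(df, subject, location, rate)
}

#' Write a sensor time-series CSV
#'
#' Values are written with 6 significant digits; a read/write round trip is
#' the identity on all fields up to that float formatting.
#'
#' @param rec an `ms_recording`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sensor_csv <- function(rec, path) {
  meta <- rec_meta(rec)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# subject: %s", meta$subject_id),
               sprintf("# location: %s", meta$body_location),
               sprintf("# sample_rate_hz: %g", meta$sample_rate_hz)), con)
  df <- as.data.frame(rec)
  df$segment <- NULL
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Construct / validate a session annotation
#'
#' Ordered labelled intervals on the device clock for the structured
#' in-clinic tasks (and free-living sleep tags). Intervals must not overlap;
#' a 30-s balance interval must last between 25 and 35 s.
#'
#' @param intervals tibble with columns `label`, `start_s`, `end_s` and
#'   optionally `rep` (repeat index, used for the three TUG trials).
#' @param subject,device optional provenance carried as attributes.
#' @return an `ms_annotation` tibble sorted by `start_s`.
#' @export
session_annotation <- function(intervals, subject = NA_character_,
                               device = NA_character_) {
  intervals <- tibble::as_tibble(intervals)
  if (nrow(intervals) == 0) {
    intervals <- tibble::tibble(label = character(), start_s = numeric(),
                                end_s = numeric(), rep = integer())
  }
  if (!"rep" %in% names(intervals)) intervals$rep <- NA_integer_
  bad <- setdiff(unique(intervals$label), ANNOTATION_LABELS)
  if (length(bad) > 0) {
    validation_error(sprintf("unknown annotation label(s): %s",
                             paste(bad, collapse = ", ")))
  }
  if (any(intervals$end_s <= intervals$start_s)) {
    validation_error("annotation interval with end_s <= start_s")
  }
  intervals <- dplyr::arrange(intervals, .data$start_s)
  if (nrow(intervals) > 1 &&
      any(intervals$start_s[-1] < intervals$end_s[-nrow(intervals)] - 1e-9)) {
    validation_error("overlapping annotation intervals")
  }
  bal <- intervals$label == "balance_30s"
  if (any(bal)) {
    dur <- intervals$end_s[bal] - intervals$start_s[bal]
    if (any(dur < 25 | dur > 35)) {
      validation_error("balance_30s interval outside 25-35 s")
    }
  }
  attr(intervals, "subject") <- subject
  attr(intervals, "device") <- device
  class(intervals) <- c("ms_annotation", class(tibble::tibble()))
  intervals
}

#' Read a session-annotation JSON file
#'
#' Schema: `{"subject": s, "device": loc, "intervals": [{"label", "start_s",
#' "end_s", "rep"}]}`. An empty interval list is valid.
#'
#' @param path path to the JSON file.
#' @return an `ms_annotation`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  iv <- j$intervals
  if (is.null(iv) || length(iv) == 0) {
    iv <- tibble::tibble(label = character(), start_s = numeric(),
                         end_s = numeric(), rep = integer())
  }
  session_annotation(tibble::as_tibble(iv),
                     subject = j$subject %||% NA_character_,
                     device = j$device %||% NA_character_)
}

#' Write a session-annotation JSON file
#' @param ann an `ms_annotation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  jsonlite::write_json(
    list(subject = attr(ann, "subject"), device = attr(ann, "device"),
         intervals = as.data.frame(ann)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read the cohort clinical-score table
#'
#' Columns: `subject`, `visit`, `edss`, `t25fw_s`, `nhpt_s`,
#' `sdmt_correct`, `lcva_correct` (an optional `fatigue_score` daily
#' ordinal is carried through if present). EDSS must lie on the half-step
#' grid 0, 0.5, ..., 10.
#'
#' @param path path to the CSV.
#' @return a validated tibble.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  df <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  need <- c("subject", "visit", "edss", "t25fw_s", "nhpt_s",
            "sdmt_correct", "lcva_correct")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    format_error(sprintf("clinical table missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  validate_clinical(df)
}

validate_clinical <- function(df) {
  ok_edss <- is.na(df$edss) | vapply(df$edss, function(e)
    any(abs(e - EDSS_GRID) < 1e-9), logical(1))
  if (!all(ok_edss)) {
    validation_error(sprintf(
      "EDSS value(s) off the half-step grid 0-10: %s",
      paste(unique(df$edss[!ok_edss]), collapse = ", ")))
  }
  if (any(df$t25fw_s <= 0, na.rm = TRUE) || any(df$nhpt_s <= 0, na.rm = TRUE)) {
    validation_error("timed-test scores must be positive")
  }
  tibble::as_tibble(df)
}

#' Write the clinical-score table
#' @param df clinical tibble (see [read_clinical_table()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Read a PVT reaction-time log
#'
#' Columns: `subject`, `session_t`, `challenge_idx`, `delay_ms`,
#' `false_start` (0/1 or logical). Delays must be non-negative and
#' challenges time-ordered within a session.
#'
#' @param path path to the CSV.
#' @return a validated `ms_pvt_log` tibble.
#' @export
read_pvt_log <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  df <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  need <- c("subject", "session_t", "challenge_idx", "delay_ms", "false_start")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    format_error(sprintf("PVT log missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  pvt_log(df)
}

#' Construct / validate a PVT log
#' @param df tibble with the PVT log columns (see [read_pvt_log()]).
#' @return an `ms_pvt_log` tibble ordered by challenge.
#' @export
pvt_log <- function(df) {
  df <- tibble::as_tibble(df)
  df$false_start <- as.logical(df$false_start)
  if (any(df$delay_ms < 0 & !df$false_start, na.rm = TRUE)) {
    validation_error("negative PVT delay on a non-false-start challenge")
  }
  df <- dplyr::arrange(df, .data$subject, .data$session_t,
                       .data$challenge_idx)
  ord <- unlist(tapply(df$challenge_idx,
                       interaction(df$subject, df$session_t, drop = TRUE),
                       function(x) all(diff(x) > 0)), use.names = FALSE)
  if (length(ord) && !all(ord)) {
    validation_error("PVT challenges not time-ordered within a session")
  }
  class(df) <- c("ms_pvt_log", class(tibble::tibble()))
  df
}

#' Write a PVT log CSV
#' @param df an `ms_pvt_log` or compatible tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pvt_log <- function(df, path) {
  out <- as.data.frame(df)
  out$false_start <- as.integer(out$false_start)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
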