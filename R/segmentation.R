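# Slice an in-clinic recording into analysis windows for the structured
# tasks. Annotation-driven slicing is exact; without an annotation a
# signal-energy changepoint fallback labels alternating quiet/active runs
# by the canonical task order (stand -> balance -> sit -> TUG x3 ->
# 2-min walk), since the clinic protocol fixes that order.

#' Segment a structured in-clinic session into task windows
#'
#' With an annotation, slicing is exact (half-open `[start, end)` sample
#' inclusion, rounding toward the interior). Without one, a rolling
#' signal-energy changepoint fallback computes the 1-s RMS of the
#' gravity-removed accelerometer magnitude on a fine hop, thresholds it
#' into quiet/active runs, and labels the runs in canonical task order.
#'
#' @param recording an `ms_recording` covering the session.
#' @param annotation an `ms_annotation`, or `NULL` for auto mode.
#' @param config list: `active_rms` (m/s^2 threshold on the 1-s RMS,
#'   default 0.5), `hop_s` (auto-mode hop, default 0.25), `min_run_s`
#'   (shortest run kept, default 3).
#' @return tibble of task windows: `label`, `start_s`, `end_s`, `rep`,
#'   `source` ("annotation" or "auto"), `confidence`.
#' @export
segment_session <- function(recording, annotation = NULL,
                            config = list()) {
  cfg <- utils::modifyList(list(active_rms = 0.5, hop_s = 0.25,
                                min_run_s = 3), config)
  t0 <- min(recording$t); t1 <- max(recording$t)
  if (!is.null(annotation)) {
    if (nrow(annotation) == 0) {
      return(tibble::tibble(label = character(), start_s = numeric(),
                            end_s = numeric(), rep = integer(),
                            source = character(), confidence = numeric()))
    }
    if (min(annotation$start_s) < t0 - 1e-9 ||
        max(annotation$end_s) > t1 + 1 / attr(recording, "sample_rate_hz")) {
      validation_error("annotation extends beyond the recording span")
    }
    return(tibble::tibble(label = annotation$label,
                          start_s = annotation$start_s,
                          end_s = annotation$end_s,
                          rep = annotation$rep,
                          source = "annotation", confidence = 1))
  }
  if (t1 - t0 < 60) validation_error("auto segmentation needs >= 60 s of data")
  fs <- attr(recording, "sample_rate_hz")
  mag <- sqrt(recording$ax^2 + recording$ay^2 + recording$az^2) - 9.81
  centers <- seq(t0 + 0.5, t1 - 0.5, by = cfg$hop_s)
  rms <- vapply(centers, function(c0) {
    idx <- recording$t >= c0 - 0.5 & recording$t < c0 + 0.5
    if (!any(idx)) return(NA_real_)
    sqrt(mean(mag[idx]^2))
  }, numeric(1))
  act <- rms > cfg$active_rms
  act[is.na(act)] <- FALSE
  if (!any(act)) {
    return(tibble::tibble(label = "stand", start_s = t0, end_s = t1,
                          rep = NA_integer_, source = "auto",
                          confidence = 1))
  }
  r <- rle(act)
  run_end <- cumsum(r$lengths)
  run_start <- c(1, head(run_end, -1) + 1)
  runs <- tibble::tibble(
    active = r$values,
    start_s = c(t0, centers[run_start[-1]] - cfg$hop_s / 2),
    end_s = c(centers[run_end[-length(run_end)]] + cfg$hop_s / 2, t1))
  runs <- runs[runs$end_s - runs$start_s >= cfg$min_run_s, ]
  quiet_labels <- c("stand", "balance_30s", "sit")
  active_labels <- c(rep("tug", 3), "walk_2min")
  qi <- 0; ai <- 0
  out <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    if (runs$active[i]) {
      ai <- ai + 1
      lab <- if (ai <= length(active_labels)) active_labels[ai] else "other"
      rep_i <- if (ai <= 3) ai else NA_integer_
    } else {
      qi <- qi + 1
      lab <- if (qi <= length(quiet_labels)) quiet_labels[qi] else "other"
      rep_i <- NA_integer_
    }
    idx <- centers >= runs$start_s[i] & centers < runs$end_s[i]
    conf <- if (any(idx)) mean((rms[idx] > cfg$active_rms) == runs$active[i],
                               na.rm = TRUE) else 0.5
    out[[i]] <- tibble::tibble(label = lab, start_s = runs$start_s[i],
                               end_s = runs$end_s[i], rep = rep_i,
                               source = "auto", confidence = conf)
  }
  dplyr::bind_rows(out)
}

#' Slice a recording to a task window
#'
#' Half-open inclusion: samples with `start_s <= t < end_s`.
#' @param recording an `ms_recording`.
#' @param window one row of a [segment_session()] result (or anything with
#'   `start_s` / `end_s`).
#' @return the sliced `ms_recording`.
#' @export
slice_window <- function(recording, window) {
  idx <- recording$t >= window$start_s & recording$t < window$end_s
  out <- recording[idx, ]
  attributes(out)[c("subject_id", "body_location", "sample_rate_hz")] <-
    attributes(recording)[c("subject_id", "body_location", "sample_rate_hz")]
  class(out) <- class(recording)
  out
}
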