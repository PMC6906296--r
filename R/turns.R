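# Turning episodes from chest or ankle yaw rate: candidate regions of high
# |yaw rate| expanded to near-zero crossings, with the turn angle taken by
# trapezoid quadrature of the *raw* yaw rate over the detected span (the
# low-passed copy is used only to find the span, so filtering cannot bias
# the angle).

#' Default turn-detection configuration
#'
#' @param lp_cutoff_hz zero-phase low-pass cutoff for detection, Hz.
#' @param candidate_deg_s |yaw| threshold that seeds a candidate region.
#' @param expand_deg_s lower threshold the region is expanded out to.
#' @param merge_gap_s candidate regions closer than this are merged, s.
#' @param min_angle_deg events with |integral| below this are discarded.
#' @param mean_mode "angle_over_duration" (|angle|/duration) or
#'   "mean_abs_yaw" (time-average of |yaw| during the event).
#' @return named list of settings.
#' @export
turn_config <- function(lp_cutoff_hz = 1.5, candidate_deg_s = 15,
                        expand_deg_s = 5, merge_gap_s = 0.2,
                        min_angle_deg = 45,
                        mean_mode = c("angle_over_duration", "mean_abs_yaw")) {
  list(lp_cutoff_hz = lp_cutoff_hz, candidate_deg_s = candidate_deg_s,
       expand_deg_s = expand_deg_s, merge_gap_s = merge_gap_s,
       min_angle_deg = min_angle_deg, mean_mode = match.arg(mean_mode))
}

# device yaw axis (body-vertical gyro channel) per body location; the chest
# device is worn upright so its z axis is near body-vertical
YAW_AXIS <- c(chest = "gz", lumbar = "gz",
              left_ankle = "gz", right_ankle = "gz",
              left_wrist = "gz", right_wrist = "gz",
              left_thigh = "gz", right_thigh = "gz")

#' Detect turning episodes in a yaw-rate trace
#'
#' @param data tibble with columns `t` (s) and `yaw` (deg/s), or a numeric
#'   vector with `fs` supplying the time base.
#' @param fs sample rate, Hz (>= 10).
#' @param config a [turn_config()].
#' @param location source body location recorded in the output
#'   ("chest" or "ankle").
#' @return tibble of turn events: `start_s`, `end_s`, `duration_s`,
#'   `angle_deg` (signed), `peak_velocity_deg_s` (max |raw yaw| in the
#'   event), `mean_velocity_deg_s`, `source_location`.
#' @export
detect_turns <- function(data, fs, config = turn_config(),
                         location = "chest") {
  if (is.numeric(data) && is.null(dim(data))) {
    data <- tibble::tibble(t = seq_along(data) / fs - 1 / fs, yaw = data)
  }
  if (fs < 10) validation_error("turn detection needs fs >= 10 Hz")
  t <- data$t; y <- data$yaw
  empty <- tibble::tibble(start_s = numeric(), end_s = numeric(),
                          duration_s = numeric(), angle_deg = numeric(),
                          peak_velocity_deg_s = numeric(),
                          mean_velocity_deg_s = numeric(),
                          source_location = character())
  if (max(t) - min(t) < 1) validation_error("turn detection needs >= 1 s")
  yf <- filtfilt_pad(y, fs, config$lp_cutoff_hz, "low")
  n <- length(y)
  seed_idx <- abs(yf) > config$candidate_deg_s
  if (!any(seed_idx)) return(empty)
  # expand each seeded run outward to the expand-threshold crossings
  r <- rle(seed_idx)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  regions <- cbind(starts[r$values], ends[r$values])
  low <- abs(yf) <= config$expand_deg_s
  for (k in seq_len(nrow(regions))) {
    i <- regions[k, 1]
    while (i > 1 && !low[i - 1]) i <- i - 1
    j <- regions[k, 2]
    while (j < n && !low[j + 1]) j <- j + 1
    regions[k, ] <- c(i, j)
  }
  # merge overlapping regions and gaps shorter than merge_gap_s
  regions <- regions[order(regions[, 1]), , drop = FALSE]
  merged <- regions[1, , drop = FALSE]
  if (nrow(regions) > 1) {
    for (k in 2:nrow(regions)) {
      gap <- t[regions[k, 1]] - t[merged[nrow(merged), 2]]
      if (gap < config$merge_gap_s) {
        merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], regions[k, 2])
      } else {
        merged <- rbind(merged, regions[k, ])
      }
    }
  }
  out <- lapply(seq_len(nrow(merged)), function(k) {
    i <- merged[k, 1]; j <- merged[k, 2]
    ang <- trapz(t[i:j], y[i:j])
    if (abs(ang) < config$min_angle_deg) return(NULL)
    dur <- t[j] - t[i]
    mean_v <- if (config$mean_mode == "angle_over_duration") abs(ang) / dur
              else mean(abs(y[i:j]))
    tibble::tibble(start_s = t[i], end_s = t[j], duration_s = dur,
                   angle_deg = ang,
                   peak_velocity_deg_s = max(abs(y[i:j])),
                   mean_velocity_deg_s = mean_v,
                   source_location = location)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) empty else res
}

#' Summarise detected turns
#'
#' Across-turn aggregates: mean |angle|, mean duration, and the
#' distribution of per-turn velocities as mean-of-peaks (`velocity_max`),
#' mean-of-means (`velocity_mean`) and the population std of per-turn mean
#' velocities (`velocity_std`). A single TUG turn cannot yield a spread, so
#' the spread is taken across the session's turns.
#'
#' @param turns output of [detect_turns()].
#' @return one-row tibble with `n_turns`, `mean_angle_deg`,
#'   `mean_duration_s`, `velocity_max_deg_s`, `velocity_mean_deg_s`,
#'   `velocity_std_deg_s`.
#' @export
summarize_turns <- function(turns) {
  if (nrow(turns) == 0) {
    return(tibble::tibble(n_turns = 0L, mean_angle_deg = NA_real_,
                          mean_duration_s = NA_real_,
                          velocity_max_deg_s = NA_real_,
                          velocity_mean_deg_s = NA_real_,
                          velocity_std_deg_s = NA_real_))
  }
  tibble::tibble(
    n_turns = nrow(turns),
    mean_angle_deg = mean(abs(turns$angle_deg)),
    mean_duration_s = mean(turns$duration_s),
    velocity_max_deg_s = mean(turns$peak_velocity_deg_s),
    velocity_mean_deg_s = mean(turns$mean_velocity_deg_s),
    velocity_std_deg_s = pop_sd(turns$mean_velocity_deg_s))
}
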