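# Gait event detection from ankle sagittal angular velocity.
#
# Event scheme: the swing phase shows a large positive sagittal pulse
# (mid-swing); stance is near-zero. Mid-swing candidates are peaks of the
# band-passed (0.5-6 Hz) signal above `peak_thresh`; toe-off is the last
# upward crossing of `onset_thresh` before the peak and heel-strike the
# first downward crossing after it. Crossings are localised on a low-passed
# copy of the raw signal (default cutoff 12 Hz) rather than the band-passed
# one - the 0.5 Hz high-pass removes the pulse-train DC and would shift the
# stance baseline away from zero, biasing threshold crossings - and refined
# to the baseline with a locally-quadratic onset projection.

#' Default gait-detection configuration
#'
#' @param peak_thresh_deg_s mid-swing peak threshold on the band-passed
#'   signal, deg/s.
#' @param onset_thresh_deg_s event-crossing threshold, deg/s.
#' @param min_peak_sep_s minimum separation between mid-swing peaks, s.
#' @param band_hz band-pass corners for peak finding, Hz.
#' @param loc_cutoff_hz low-pass cutoff for event localisation, Hz
#'   (capped below the Nyquist frequency at run time).
#' @return named list of settings.
#' @export
gait_config <- function(peak_thresh_deg_s = 40, onset_thresh_deg_s = 10,
                        min_peak_sep_s = 0.4, band_hz = c(0.5, 6),
                        loc_cutoff_hz = 12) {
  list(peak_thresh_deg_s = peak_thresh_deg_s,
       onset_thresh_deg_s = onset_thresh_deg_s,
       min_peak_sep_s = min_peak_sep_s, band_hz = band_hz,
       loc_cutoff_hz = loc_cutoff_hz)
}

#' Detect gait events in a sagittal angular-velocity trace
#'
#' One trace corresponds to one foot; left/right streams are processed
#' independently (the device body location identifies the foot).
#'
#' @param data tibble with columns `t` (s) and `gyro` (deg/s), or a plain
#'   numeric vector of samples (then `fs` supplies the time base).
#' @param fs sample rate, Hz (>= 20).
#' @param config a [gait_config()].
#' @param foot "left" or "right", recorded in the output.
#' @return tibble of strides sorted by time: `foot`, `toe_off_t`,
#'   `heel_strike_t`, `swing_time_s`, `stance_time_s`, `stride_time_s`.
#'   Stance/stride need the next toe-off, so they are `NA` on the final
#'   stride of a bout. No detected peaks gives an empty tibble.
#' @export
detect_gait_events <- function(data, fs, config = gait_config(),
                               foot = "left") {
  if (is.numeric(data) && is.null(dim(data))) {
    data <- tibble::tibble(t = seq_along(data) / fs - 1 / fs, gyro = data)
  }
  if (fs < 20) validation_error("gait detection needs fs >= 20 Hz")
  y <- data$gyro
  t <- data$t
  empty <- tibble::tibble(foot = character(), toe_off_t = numeric(),
                          heel_strike_t = numeric(), swing_time_s = numeric(),
                          stance_time_s = numeric(), stride_time_s = numeric())
  if (length(y) < 2 || (max(t) - min(t)) < 2) {
    validation_error("gait detection needs >= 2 s of signal")
  }
  ybp <- filtfilt_pad(y, fs, config$band_hz, "pass")
  loc_cut <- min(config$loc_cutoff_hz, 0.45 * fs)
  ylp <- filtfilt_pad(y, fs, loc_cut, "low")
  n <- length(y)
  pk <- which(diff(sign(diff(ybp))) == -2) + 1L
  pk <- pk[ybp[pk] > config$peak_thresh_deg_s]
  if (length(pk) == 0) return(empty)
  # enforce minimum separation, keeping the larger peak
  keep <- logical(length(pk))
  last_t <- -Inf; last_i <- 0
  for (i in seq_along(pk)) {
    if (t[pk[i]] - last_t >= config$min_peak_sep_s) {
      keep[i] <- TRUE; last_t <- t[pk[i]]; last_i <- i
    } else if (ybp[pk[i]] > ybp[pk[last_i]]) {
      keep[last_i] <- FALSE; keep[i] <- TRUE
      last_t <- t[pk[i]]; last_i <- i
    }
  }
  pk <- pk[keep]
  thr <- config$onset_thresh_deg_s
  ev <- lapply(pk, function(p) {
    i <- p
    while (i > 1 && ylp[i - 1] > thr) i <- i - 1
    j <- p
    while (j < n && ylp[j + 1] > thr) j <- j + 1
    c(to = refine_onset(t, ylp, i, fs, "onset"),
      hs = refine_onset(t, ylp, j, fs, "offset"))
  })
  to <- vapply(ev, `[[`, numeric(1), "to")
  hs <- vapply(ev, `[[`, numeric(1), "hs")
  ok <- hs > to
  to <- to[ok]; hs <- hs[ok]
  if (length(to) == 0) return(empty)
  nxt <- c(to[-1], NA_real_)
  tibble::tibble(foot = foot, toe_off_t = to, heel_strike_t = hs,
                 swing_time_s = hs - to,
                 stance_time_s = nxt - hs,
                 stride_time_s = nxt - to)
}

#' Summarise gait over a mobility task window
#'
#' Medians (not means) of the per-stride phase durations, a step count, and
#' the mobility activity time, taken as the duration of the mobility task
#' window (for a TUG, the time to complete the test). Strides whose
#' toe-off falls outside the window are excluded.
#'
#' @param strides output of [detect_gait_events()] (both feet may be bound
#'   together).
#' @param mobility_window a task-window row with label `tug` or
#'   `walk_2min`.
#' @return one-row tibble: `n_steps`, `median_stance_s`, `median_swing_s`,
#'   `mobility_activity_time_s`, `low_confidence` (fewer than 3 complete
#'   strides).
#' @export
summarize_gait <- function(strides, mobility_window) {
  if (!mobility_window$label %in% c("tug", "walk_2min")) {
    validation_error("mobility window must be a tug or walk_2min window")
  }
  inw <- strides[strides$toe_off_t >= mobility_window$start_s &
                 strides$toe_off_t < mobility_window$end_s, ]
  complete <- inw[!is.na(inw$stance_time_s), ]
  tibble::tibble(
    n_steps = nrow(inw),
    median_stance_s = if (nrow(complete)) median(complete$stance_time_s)
                      else NA_real_,
    median_swing_s = if (nrow(inw)) median(inw$swing_time_s) else NA_real_,
    mobility_activity_time_s = mobility_window$end_s - mobility_window$start_s,
    low_confidence = nrow(complete) < 3)
}
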