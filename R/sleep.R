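# Sleep and fatigue: HRV epochs from inter-beat intervals during tagged
# sleep, a transparent RMSSD-threshold REM/NREM rule (stand-in for the
# original trained model - REM carries distinctly higher short-term HRV
# than NREM), leg-movement rate from ankle accelerometry, and PVT
# reaction-time features.

#' RMSSD threshold of the REM/NREM epoch rule, ms
#'
#' Fixed decision boundary between the night generator's default stage
#' parameters (RMSSD scale 45 ms in REM vs 20 ms in NREM): their geometric
#' mean, 30 ms. Chosen once from those defaults, not refit per night.
#' @export
REM_RMSSD_THRESHOLD_MS <- 30

#' Per-epoch HRV features from an IBI series
#'
#' Ectopic filter: IBIs outside 300-2000 ms, or differing more than 20%
#' from an 11-beat running median, are dropped before epoching. Epochs
#' with fewer than `min_beats` remaining beats are flagged invalid.
#'
#' @param ibi tibble with columns `t` (s) and `ibi_ms`.
#' @param epoch_s epoch length, s (default 300 = 5 min).
#' @param min_beats minimum beats for a valid epoch.
#' @return tibble per epoch: `epoch`, `start_s`, `n_beats`, `mean_ibi_ms`,
#'   `sdnn_ms`, `rmssd_ms`, `valid`.
#' @export
hrv_epochs <- function(ibi, epoch_s = 300, min_beats = 30) {
  ibi <- tibble::as_tibble(ibi)
  if (nrow(ibi) == 0) validation_error("empty IBI series")
  x <- ibi$ibi_ms
  runmed_ref <- stats::runmed(x, k = min(11, length(x) - (1 - length(x) %% 2)),
                              endrule = "median")
  keep <- x >= 300 & x <= 2000 & abs(x - runmed_ref) <= 0.2 * runmed_ref
  ibi <- ibi[keep, ]
  if (nrow(ibi) == 0) validation_error("no IBIs survive the ectopic filter")
  t0 <- min(ibi$t)
  ibi$epoch <- floor((ibi$t - t0) / epoch_s)
  ibi |>
    dplyr::group_by(.data$epoch) |>
    dplyr::summarise(
      start_s = t0 + .data$epoch[1] * epoch_s,
      n_beats = dplyr::n(),
      mean_ibi_ms = mean(.data$ibi_ms),
      sdnn_ms = if (dplyr::n() > 1) stats::sd(.data$ibi_ms) else 0,
      rmssd_ms = if (dplyr::n() > 1)
        sqrt(mean(diff(.data$ibi_ms)^2)) else 0,
      .groups = "drop") |>
    dplyr::mutate(valid = .data$n_beats >= min_beats)
}

#' Estimate REM percentage from epoch HRV features
#'
#' Two-class rule: an epoch is REM when its RMSSD exceeds the threshold;
#' the epoch sequence is then smoothed with a 3-epoch majority vote.
#' Requires at least `min_epochs` valid epochs.
#'
#' @param epochs output of [hrv_epochs()].
#' @param threshold_ms decision threshold
#'   (default [REM_RMSSD_THRESHOLD_MS]).
#' @param smooth apply the 3-epoch majority smoothing.
#' @param min_epochs minimum number of valid epochs.
#' @return list: `rem_percent` (of valid epochs), `stages` (tibble with
#'   per-epoch stage estimates).
#' @export
estimate_rem_percent <- function(epochs, threshold_ms = REM_RMSSD_THRESHOLD_MS,
                                 smooth = TRUE, min_epochs = 6) {
  v <- epochs[epochs$valid, ]
  if (nrow(v) == 0) validation_error("no valid epochs")
  if (nrow(v) < min_epochs) {
    validation_error(sprintf("fewer than %d valid epochs", min_epochs))
  }
  stage <- ifelse(v$rmssd_ms > threshold_ms, "REM", "NREM")
  if (smooth) stage <- majority3(stage)
  list(rem_percent = 100 * mean(stage == "REM"),
       stages = tibble::tibble(epoch = v$epoch, start_s = v$start_s,
                               rmssd_ms = v$rmssd_ms, stage = stage))
}

#' Leg-movement rate during tagged sleep
#'
#' A movement event is an excursion of the band-passed (0.5-10 Hz) ankle
#' acceleration magnitude above threshold lasting at least `min_dur_s`;
#' events starting within the refractory period of an accepted event are
#' absorbed into it. The rate is events per tagged hour.
#'
#' @param recording ankle `ms_recording` restricted to the tagged sleep
#'   interval (at least 1 h).
#' @param threshold_ms2 excursion threshold, m/s^2.
#' @param min_dur_s minimum excursion duration, s.
#' @param refractory_s dead time after an accepted event, s.
#' @return list: `rate_per_h`, `n_events`, `events` (tibble `start_s`,
#'   `end_s`).
#' @export
leg_movement_rate <- function(recording, threshold_ms2 = 0.1,
                              min_dur_s = 0.5, refractory_s = 5) {
  fs <- attr(recording, "sample_rate_hz")
  # half-open sample coverage: n samples at fs span n/fs seconds
  dur_h <- (max(recording$t) - min(recording$t) + 1 / fs) / 3600
  if (dur_h < 1) validation_error("tagged sleep shorter than 1 h")
  mag <- sqrt(recording$ax^2 + recording$ay^2 + recording$az^2)
  hi <- min(10, 0.45 * fs)
  bp <- filtfilt_pad(mag, fs, c(0.5, hi), "pass")
  # RMS envelope (0.3 s) so an oscillatory burst registers as one sustained
  # excursion rather than a train of half-cycles
  nw <- max(1L, as.integer(round(0.3 * fs)))
  cs <- cumsum(c(0, bp^2))
  n <- length(bp)
  lo_i <- pmax(seq_len(n) - nw %/% 2, 1)
  hi_i <- pmin(seq_len(n) + nw %/% 2, n)
  env <- sqrt((cs[hi_i + 1] - cs[lo_i]) / (hi_i - lo_i + 1))
  above <- env > threshold_ms2
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  runs <- tibble::tibble(start_s = recording$t[starts[r$values]],
                         end_s = recording$t[ends[r$values]])
  runs <- runs[runs$end_s - runs$start_s >= min_dur_s, ]
  acc <- list(); last <- -Inf
  for (i in seq_len(nrow(runs))) {
    if (runs$start_s[i] - last >= refractory_s) {
      acc[[length(acc) + 1]] <- runs[i, ]
      last <- runs$start_s[i]
    }
  }
  ev <- dplyr::bind_rows(acc)
  list(rate_per_h = nrow(ev) / dur_h, n_events = nrow(ev), events = ev)
}

#' PVT fatigue features from a reaction-time log
#'
#' Mean response delay over the whole (nominally 3-minute) test and over
#' the first 1, 3, 5 and 7 valid challenges. False starts are excluded
#' from all means; first-k means use the first k valid challenges (fewer
#' if the test had fewer).
#'
#' @param log an `ms_pvt_log` (one subject-session).
#' @return one-row tibble: `mean_delay_total_ms`, `mean_delay_first_1_ms`,
#'   `..._3_ms`, `..._5_ms`, `..._7_ms`, `n_challenges`, `n_false_starts`.
#' @export
pvt_features <- function(log) {
  valid <- log$delay_ms[!log$false_start]
  if (length(valid) == 0) validation_error("no valid PVT challenges")
  firstk <- function(k) mean(head(valid, k))
  tibble::tibble(
    mean_delay_total_ms = mean(valid),
    mean_delay_first_1_ms = firstk(1),
    mean_delay_first_3_ms = firstk(3),
    mean_delay_first_5_ms = firstk(5),
    mean_delay_first_7_ms = firstk(7),
    n_challenges = length(valid),
    n_false_starts = sum(log$false_start))
}
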