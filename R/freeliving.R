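# Free-living streams: windowed featurisation, a transparent threshold
# activity classifier (stand-in for the original trained classifier - the
# downstream analyses need only the labels idle/walking/running/other),
# gait/turn extraction inside walking bouts, daily aggregates, and
# wear-compliance grouping.

#' Default free-living configuration
#'
#' @param idle_var_th accel-magnitude variance below which a window is
#'   idle, (m/s^2)^2.
#' @param walk_band_hz dominant-frequency band read as walking (stride
#'   rate), Hz.
#' @param run_band_hz dominant-frequency band read as running, Hz.
#' @param periodicity_th minimum fraction of spectral power at the
#'   dominant frequency (+/- 1 bin) for a periodic label.
#' @param run_var_th minimum accel variance for running, (m/s^2)^2.
#' @param wear_var_floor accel variance above which a window counts as
#'   worn, (m/s^2)^2.
#' @param min_strides_day minimum strides for a daily gait median.
#' @return named list of settings.
#' @export
freeliving_config <- function(idle_var_th = 0.05, walk_band_hz = c(0.6, 1.4),
                              run_band_hz = c(1.4, 3.5),
                              periodicity_th = 0.25, run_var_th = 4,
                              wear_var_floor = 1e-5,
                              min_strides_day = 10) {
  list(idle_var_th = idle_var_th, walk_band_hz = walk_band_hz,
       run_band_hz = run_band_hz, periodicity_th = periodicity_th,
       run_var_th = run_var_th, wear_var_floor = wear_var_floor,
       min_strides_day = min_strides_day)
}

#' Windowed feature extraction from a free-living recording
#'
#' Fixed windows over the stream; windows with a data gap (fewer than 90%
#' of the expected samples) are skipped.
#'
#' @param recording an `ms_recording` (wrist accelerometer for activity
#'   classification).
#' @param window_s,hop_s window length and hop, s.
#' @return tibble, one row per window: `start_s`, `end_s`, `accel_mean`,
#'   `accel_var`, `sma` (signal magnitude area), `dom_freq_hz` (spectral
#'   peak in 0.3-5 Hz, 0 when the window has no appreciable oscillation),
#'   `periodicity`, `gyro_rms`.
#' @export
extract_windows <- function(recording, window_s = 5, hop_s = 5) {
  fs <- attr(recording, "sample_rate_hz")
  t0 <- min(recording$t); t1 <- max(recording$t)
  if (t1 - t0 < window_s) validation_error("less than one window of data")
  # the stream covers [t0, t1 + 1/fs) in half-open sample terms
  starts <- seq(t0, t1 + 1 / fs - window_s + 1e-9, by = hop_s)
  need <- 0.9 * window_s * fs
  # position ranges of the half-open windows on the sorted time base
  lo_all <- findInterval(starts - 1e-9, recording$t) + 1L
  hi_all <- findInterval(starts + window_s - 1e-9, recording$t)
  feat <- vapply(seq_along(starts), function(w) {
    if (hi_all[w] < lo_all[w]) return(rep(NA_real_, 6))
    idx <- lo_all[w]:hi_all[w]
    if (length(idx) < need) return(rep(NA_real_, 6))
    ax <- recording$ax[idx]; ay <- recording$ay[idx]; az <- recording$az[idx]
    mag <- sqrt(ax^2 + ay^2 + az^2)
    magc <- mag - mean(mag)
    dev <- abs(ax - mean(ax)) + abs(ay - mean(ay)) + abs(az - mean(az))
    # dominant frequency of the gravity-removed magnitude, 0.3-5 Hz
    # (widened past the walking/running decision bands so band-edge
    # rates are still localised)
    sp <- Mod(stats::fft(magc))^2
    nf <- length(magc)
    freqs <- (seq_len(nf) - 1) * fs / nf
    band <- freqs >= 0.3 & freqs <= min(5, fs / 2 - 0.1)
    dom <- 0; periodicity <- 0
    if (any(band) && sum(sp[band]) > 0 && stats::var(mag) >= 1e-10) {
      wb <- which(band)
      bi <- wb[which.max(sp[band])]
      dom <- freqs[bi]
      neigh <- intersect((bi - 1):(bi + 1), wb)
      tot <- sum(sp[freqs > 0.05 & freqs <= fs / 2])
      if (tot > 0) periodicity <- sum(sp[neigh]) / tot
    }
    gx <- recording$gx[idx]; gy <- recording$gy[idx]; gz <- recording$gz[idx]
    c(mean(mag), stats::var(mag), mean(dev), dom, periodicity,
      sqrt(mean(gx^2 + gy^2 + gz^2)))
  }, numeric(6))
  keep <- !is.na(feat[1, ])
  tibble::new_tibble(list(
    start_s = starts[keep], end_s = starts[keep] + window_s,
    accel_mean = feat[1, keep], accel_var = feat[2, keep],
    sma = feat[3, keep], dom_freq_hz = feat[4, keep],
    periodicity = feat[5, keep], gyro_rms = feat[6, keep]),
    nrow = sum(keep))
}

#' Classify windowed features into activity bouts
#'
#' Decision rules (stand-in for the original trained classifier, same label
#' set): variance below the idle threshold gives idle; a dominant frequency
#' in the stride-rate band with sufficient periodicity gives walking; in
#' the running band with high magnitude gives running; anything else is
#' other. Labels are smoothed with a 3-window majority vote and contiguous
#' same-label windows merge into bouts.
#'
#' @param features output of [extract_windows()].
#' @param config a [freeliving_config()].
#' @return tibble of bouts: `label`, `start_s`, `end_s`, `confidence`
#'   (fraction of the bout's windows whose raw label matches).
#' @export
classify_activity <- function(features, config = freeliving_config()) {
  if (nrow(features) == 0) {
    return(tibble::tibble(label = character(), start_s = numeric(),
                          end_s = numeric(), confidence = numeric()))
  }
  raw <- with(features, dplyr::case_when(
    accel_var < config$idle_var_th ~ "idle",
    dom_freq_hz >= config$walk_band_hz[1] &
      dom_freq_hz <= config$walk_band_hz[2] &
      periodicity > config$periodicity_th ~ "walking",
    dom_freq_hz > config$run_band_hz[1] &
      dom_freq_hz <= config$run_band_hz[2] &
      accel_var > config$run_var_th ~ "running",
    TRUE ~ "other"))
  smooth <- majority3(raw)
  r <- rle(smooth)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  tibble::tibble(
    label = r$values,
    start_s = features$start_s[starts],
    end_s = features$end_s[ends],
    confidence = vapply(seq_along(starts), function(k)
      mean(raw[starts[k]:ends[k]] == r$values[k]), numeric(1)))
}

#' Run the clinic gait/turn extractors inside walking bouts
#'
#' @param recordings named list with optional elements `ankle` (sagittal
#'   gyro source) and `chest` (yaw source), each an `ms_recording`.
#' @param bouts output of [classify_activity()]; only walking bouts are
#'   analysed.
#' @param gait_cfg,turn_cfg extractor configurations.
#' @return list with `strides` and `turns` tibbles, each tagged with the
#'   originating bout's `bout_start_s`. A missing ankle stream yields no
#'   gait features (not an error).
#' @export
analyze_walking_bouts <- function(recordings, bouts,
                                  gait_cfg = gait_config(),
                                  turn_cfg = turn_config()) {
  wb <- bouts[bouts$label == "walking", ]
  strides <- list(); turns <- list()
  for (i in seq_len(nrow(wb))) {
    w <- wb[i, ]
    if (!is.null(recordings$ankle)) {
      rec <- slice_window(recordings$ankle, w)
      fs <- attr(rec, "sample_rate_hz")
      if (nrow(rec) > 2 * fs) {
        st <- detect_gait_events(
          tibble::tibble(t = rec$t, gyro = rec$gy), fs, gait_cfg,
          foot = if (grepl("left", attr(rec, "body_location"))) "left"
                 else "right")
        if (nrow(st)) strides[[length(strides) + 1]] <-
            dplyr::mutate(st, bout_start_s = w$start_s)
      }
    }
    if (!is.null(recordings$chest)) {
      rec <- slice_window(recordings$chest, w)
      fs <- attr(rec, "sample_rate_hz")
      if (nrow(rec) > fs) {
        tu <- detect_turns(tibble::tibble(t = rec$t, yaw = rec$gz), fs,
                           turn_cfg, location = "chest")
        if (nrow(tu)) turns[[length(turns) + 1]] <-
            dplyr::mutate(tu, bout_start_s = w$start_s)
      }
    }
  }
  list(strides = dplyr::bind_rows(strides), turns = dplyr::bind_rows(turns))
}

#' Daily aggregates of free-living features
#'
#' @param bouts activity bouts of one day.
#' @param strides stride table of that day (may be empty).
#' @param features window features of that day (wear detection: a window
#'   is worn when its accel variance exceeds the noise floor or its gyro
#'   RMS is appreciable).
#' @param day day index recorded in the output.
#' @param config a [freeliving_config()].
#' @return one-row tibble: `day`, `n_strides`, `median_stance_s`,
#'   `median_swing_s`, `idle_minutes`, `worn_hours`, `gait_valid`.
#' @export
daily_features <- function(bouts, strides, features, day = 1L,
                           config = freeliving_config()) {
  worn <- features$accel_var > config$wear_var_floor |
    features$gyro_rms > 0.5
  worn_hours <- sum((features$end_s - features$start_s)[worn]) / 3600
  idle_minutes <- sum((bouts$end_s - bouts$start_s)[bouts$label == "idle"]) / 60
  if (is.null(strides) || !"stance_time_s" %in% names(strides)) {
    strides <- tibble::tibble(stance_time_s = numeric(),
                              swing_time_s = numeric())
  }
  complete <- strides[!is.na(strides$stance_time_s), , drop = FALSE]
  nst <- nrow(complete)
  ok <- nst >= config$min_strides_day
  tibble::tibble(
    day = day,
    n_strides = nst,
    median_stance_s = if (ok) median(complete$stance_time_s) else NA_real_,
    median_swing_s = if (ok) median(complete$swing_time_s) else NA_real_,
    idle_minutes = idle_minutes,
    worn_hours = worn_hours,
    gait_valid = ok)
}

#' Classify wear compliance against the protocol target
#'
#' Rules on weekly worn hours as a fraction of target: `low` - mean weekly
#' wear below 20% of target; `declining` - first-two-week mean at or above
#' 80% and final-two-week mean at or below 60%; `high` - at or above 80%
#' in all but at most two weeks. Precedence low > declining > high;
#' a pattern matching none of the three is reported as declining.
#'
#' @param weekly tibble with columns `subject`, `week`, `worn_hours`.
#' @param target_hours protocol target per week (> 0).
#' @return tibble: `subject`, `mean_pct`, `group`.
#' @export
compliance <- function(weekly, target_hours) {
  if (target_hours <= 0) validation_error("target_hours must be positive")
  weekly |>
    dplyr::group_by(.data$subject) |>
    dplyr::arrange(.data$week, .by_group = TRUE) |>
    dplyr::summarise(
      mean_pct = 100 * mean(.data$worn_hours) / target_hours,
      group = {
        pct <- 100 * .data$worn_hours / target_hours
        nw <- length(pct)
        if (mean(pct) < 20) "low"
        else if (nw >= 4 && mean(pct[1:2]) >= 80 &&
                 mean(pct[(nw - 1):nw]) <= 60) "declining"
        else if (sum(pct < 80) <= 2) "high"
        else "declining"
      },
      .groups = "drop")
}
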