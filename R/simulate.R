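# Signal-level generators. Every generator emits its ground truth alongside
# the signal (no hidden state), so the extractors can be tested against an
# independent reading of the event schedule. Swing and turn pulses are
# raised cosines: smooth, band-limited, and analytically integrable, which
# makes closed-form oracles possible.

#' Simulate an ankle sagittal gyroscope trace during walking
#'
#' Signal model: near-zero angular velocity in stance and one smooth
#' positive raised-cosine swing pulse per step, alternating feet. The two
#' feet are half a stride period out of phase. Per-foot true stance time is
#' `stance_fraction / stride_rate_hz`, swing `(1 - stance_fraction) /
#' stride_rate_hz`.
#'
#' @param stride_rate_hz strides per second per foot (cadence / 2 / 60).
#' @param stance_fraction fraction of the stride spent in stance, in (0, 1).
#' @param duration_s bout duration, seconds (at least 2 strides).
#' @param fs sample rate, Hz (>= 20; the swing pulse is under-sampled below).
#' @param noise_sd additive Gaussian noise, deg/s.
#' @param seed RNG seed (reproducible traces under the same seed).
#' @param swing_peak_deg_s peak sagittal angular velocity at mid-swing.
#' @param start_s time of the first left toe-off.
#' @return list with `trace` (tibble `t`, `gyro_left`, `gyro_right`, deg/s)
#'   and `truth` (tibble `foot`, `step`, `toe_off_t`, `heel_strike_t`,
#'   `stance_time_s`, `swing_time_s`).
#' @export
simulate_gait_bout <- function(stride_rate_hz, stance_fraction, duration_s,
                               fs = 100, noise_sd = 0, seed = 1,
                               swing_peak_deg_s = 250, start_s = 0) {
  if (stance_fraction <= 0 || stance_fraction >= 1) {
    validation_error("stance_fraction must lie in (0, 1)")
  }
  if (fs < 20) validation_error("fs below 20 Hz under-samples the swing pulse")
  stride_T <- 1 / stride_rate_hz
  if (duration_s < 2 * stride_T) {
    validation_error("duration shorter than two strides")
  }
  swing_T <- (1 - stance_fraction) * stride_T
  t <- seq(0, duration_s, by = 1 / fs)
  mk_foot <- function(first_toe_off) {
    tos <- seq(first_toe_off, duration_s - swing_T, by = stride_T)
    y <- numeric(length(t))
    for (t0 in tos) {
      idx <- t >= t0 & t <= t0 + swing_T
      y[idx] <- swing_peak_deg_s * (1 - cos(2 * pi * (t[idx] - t0) / swing_T)) / 2
    }
    list(y = y, toe_off = tos)
  }
  left <- mk_foot(start_s)
  right <- mk_foot(start_s + stride_T / 2)
  set.seed(seed)
  nz <- function(y) if (noise_sd > 0) y + rnorm(length(y), 0, noise_sd) else y
  tos <- c(left$toe_off, right$toe_off)
  truth <- tibble::new_tibble(list(
    foot = rep(c("left", "right"), c(length(left$toe_off),
                                     length(right$toe_off))),
    step = c(seq_along(left$toe_off), seq_along(right$toe_off)),
    toe_off_t = tos,
    heel_strike_t = tos + swing_T,
    stance_time_s = rep(stance_fraction * stride_T, length(tos)),
    swing_time_s = rep(swing_T, length(tos))), nrow = length(tos))
  list(trace = tibble::tibble(t = t, gyro_left = nz(left$y),
                              gyro_right = nz(right$y)),
       truth = truth)
}

#' Simulate a yaw-rate turn pulse
#'
#' Raised-cosine angular-velocity pulse
#' `omega(t) = A (1 - cos(2 pi t / T)) / 2` with `A = 2 * angle / T`, so the
#' integral over the pulse equals `angle_deg` exactly, the peak rate is `A`
#' and the mean rate is `angle / T`.
#'
#' @param angle_deg signed total turn angle, degrees.
#' @param duration_s pulse duration `T`, seconds (> 0).
#' @param fs sample rate, Hz.
#' @param noise_sd additive Gaussian noise, deg/s.
#' @param seed RNG seed.
#' @param margin_s zero-rate margin prepended/appended around the pulse.
#' @return list with `trace` (tibble `t`, `yaw` deg/s) and `truth`
#'   (one-row tibble: `start_s`, `end_s`, `angle_deg`, `duration_s`,
#'   `peak_deg_s`, `mean_deg_s`).
#' @export
simulate_turn <- function(angle_deg, duration_s, fs = 100, noise_sd = 0,
                          seed = 1, margin_s = 1) {
  if (duration_s <= 0) validation_error("turn duration must be positive")
  A <- 2 * angle_deg / duration_s
  t <- seq(0, duration_s + 2 * margin_s, by = 1 / fs)
  y <- numeric(length(t))
  idx <- t >= margin_s & t <= margin_s + duration_s
  y[idx] <- A * (1 - cos(2 * pi * (t[idx] - margin_s) / duration_s)) / 2
  set.seed(seed)
  if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
  list(trace = tibble::tibble(t = t, yaw = y),
       truth = tibble::tibble(start_s = margin_s,
                              end_s = margin_s + duration_s,
                              angle_deg = angle_deg, duration_s = duration_s,
                              peak_deg_s = abs(A),
                              mean_deg_s = abs(angle_deg) / duration_s))
}

#' Simulate a 2-D postural sway displacement track
#'
#' Two models: `sinusoid` — `ml(t) = A_ml sin(2 pi f t)`,
#' `ap(t) = A_ap sin(2 pi f t + pi/2)` (quadrature phase, closed-form path
#' length `4 A f T` per axis); `filtered_noise` — independent low-passed
#' Gaussian walks rescaled so each axis has RMS amplitude `A / sqrt(2)`
#' (matching the sinusoid's RMS for the same nominal amplitude).
#'
#' @param model "sinusoid" or "filtered_noise".
#' @param A_ml_mm,A_ap_mm mediolateral / anterior-posterior amplitudes, mm
#'   (non-negative).
#' @param f_hz sway frequency (sinusoid) or low-pass cutoff (noise), Hz.
#' @param duration_s track duration (the balance window is nominally 30 s).
#' @param fs sample rate, Hz.
#' @param seed RNG seed (used by the noise model).
#' @param derive_accel if `TRUE`, also return the horizontal acceleration
#'   trace implied by the track (second central difference, m/s^2).
#' @return list with `track` (tibble `t`, `ml_mm`, `ap_mm`), `truth`
#'   (model parameters and, for the sinusoid, analytic per-axis path
#'   length and range), and optionally `accel` (tibble `t`, `a_ml`, `a_ap`).
#' @export
simulate_sway_track <- function(model = c("sinusoid", "filtered_noise"),
                                A_ml_mm = 2, A_ap_mm = 2, f_hz = 0.5,
                                duration_s = 30, fs = 100, seed = 1,
                                derive_accel = FALSE) {
  model <- match.arg(model)
  if (A_ml_mm < 0 || A_ap_mm < 0) {
    validation_error("sway amplitudes must be non-negative")
  }
  t <- seq(0, duration_s, by = 1 / fs)
  if (model == "sinusoid") {
    ml <- A_ml_mm * sin(2 * pi * f_hz * t)
    ap <- A_ap_mm * sin(2 * pi * f_hz * t + pi / 2)
    truth <- tibble::tibble(
      model = model, A_ml_mm = A_ml_mm, A_ap_mm = A_ap_mm, f_hz = f_hz,
      path_ml_mm = 4 * A_ml_mm * f_hz * duration_s,
      path_ap_mm = 4 * A_ap_mm * f_hz * duration_s,
      range_ml_mm = 2 * A_ml_mm, range_ap_mm = 2 * A_ap_mm)
  } else {
    set.seed(seed)
    mk <- function(A) {
      w <- rnorm(length(t))
      x <- filtfilt_pad(w, fs, f_hz, "low")
      if (A == 0 || stats::sd(x) == 0) return(rep(0, length(t)))
      (x - mean(x)) / stats::sd(x) * (A / sqrt(2))
    }
    ml <- mk(A_ml_mm)
    ap <- mk(A_ap_mm)
    truth <- tibble::tibble(model = model, A_ml_mm = A_ml_mm,
                            A_ap_mm = A_ap_mm, f_hz = f_hz,
                            path_ml_mm = NA_real_, path_ap_mm = NA_real_,
                            range_ml_mm = NA_real_, range_ap_mm = NA_real_)
  }
  out <- list(track = tibble::tibble(t = t, ml_mm = ml, ap_mm = ap),
              truth = truth)
  if (derive_accel) {
    d2 <- function(x) {
      n <- length(x)
      a <- c(0, (x[-c(1, 2)] - 2 * x[-c(1, n)] + x[-c(n - 1, n)]) * fs^2, 0)
      a[1] <- a[2]; a[n] <- a[n - 1]
      a / 1000  # mm/s^2 -> m/s^2
    }
    out$accel <- tibble::tibble(t = t, a_ml = d2(ml), a_ap = d2(ap))
  }
  out
}

#' Simulate a night of inter-beat intervals with a known stage sequence
#'
#' Per-beat IBIs follow an AR(1) process around the stage mean; the
#' innovation variance is set per stage so the short-term variability
#' (RMSSD scale) matches the stage parameter. Defaults plant higher
#' short-term variability in REM (45 ms) than NREM (20 ms), the separation
#' the HRV sleep-stage rule relies on.
#'
#' @param stage_schedule tibble with columns `stage` (REM/NREM/WAKE) and
#'   `minutes`.
#' @param stage_params named list per stage: `mean_ibi_ms`, `rmssd_ms`.
#' @param seed RNG seed.
#' @param ar_phi AR(1) coefficient of the beat-to-beat process.
#' @return list with `ibi` (tibble `t` seconds, `ibi_ms`), `truth`
#'   (schedule with epoch times and the true REM percentage of sleep time).
#' @export
simulate_ibi_night <- function(stage_schedule,
                               stage_params = default_stage_params(),
                               seed = 1, ar_phi = 0.3) {
  stage_schedule <- tibble::as_tibble(stage_schedule)
  if (nrow(stage_schedule) == 0) validation_error("empty stage schedule")
  if (!all(stage_schedule$stage %in% c("REM", "NREM", "WAKE"))) {
    validation_error("stages must be REM, NREM or WAKE")
  }
  set.seed(seed)
  t_cur <- 0
  ts <- list(); ib <- list(); seg <- list()
  prev <- NULL
  for (i in seq_len(nrow(stage_schedule))) {
    st <- stage_schedule$stage[i]
    dur_s <- stage_schedule$minutes[i] * 60
    p <- stage_params[[st]]
    # RMSSD of stationary AR(1): sqrt(2) * sigma_x * sqrt(1 - phi);
    # with innovation sd s_e, sigma_x^2 = s_e^2 / (1 - phi^2)
    sigma_x <- p$rmssd_ms / sqrt(2 * (1 - ar_phi))
    s_e <- sigma_x * sqrt(1 - ar_phi^2)
    t_end <- t_cur + dur_s
    x <- if (is.null(prev)) rnorm(1, 0, sigma_x) else prev
    while (t_cur < t_end) {
      x <- ar_phi * x + rnorm(1, 0, s_e)
      ibi <- max(p$mean_ibi_ms + x, 250)
      ts[[length(ts) + 1L]] <- t_cur
      ib[[length(ib) + 1L]] <- ibi
      t_cur <- t_cur + ibi / 1000
    }
    prev <- x
    seg[[i]] <- tibble::tibble(stage = st, start_s = t_end - dur_s,
                               end_s = t_end, minutes = stage_schedule$minutes[i])
    t_cur <- t_end
  }
  sched <- dplyr::bind_rows(seg)
  sleep_min <- sum(sched$minutes[sched$stage != "WAKE"])
  rem_min <- sum(sched$minutes[sched$stage == "REM"])
  list(ibi = tibble::tibble(t = unlist(ts), ibi_ms = unlist(ib)),
       truth = list(schedule = sched,
                    rem_percent = if (sleep_min > 0) 100 * rem_min / sleep_min
                                  else NA_real_))
}

#' Default per-stage IBI parameters of the night generator
#'
#' Mean IBI and short-term variability (RMSSD scale) per sleep stage.
#' @return named list of per-stage parameter lists.
#' @export
default_stage_params <- function() {
  list(REM  = list(mean_ibi_ms = 850,  rmssd_ms = 45),
       NREM = list(mean_ibi_ms = 1000, rmssd_ms = 20),
       WAKE = list(mean_ibi_ms = 750,  rmssd_ms = 35))
}
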