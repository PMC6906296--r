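# Cohort-level synthetic data: latent disability drives gait, turn, sway,
# activity, sleep and clinical scores through monotone effect functions.
# Effect signs mirror the in-clinic and free-living correlation structure
# this package is built to recover: with worsening disability, stance time,
# sway amplitude, idle fraction, leg movements and PVT delay increase;
# turn velocity, REM fraction and resting HRV decrease.

#' Effect configuration of the synthetic cohort
#'
#' Each entry maps the latent disability `d` in \[0, 1\] to a true subject
#' parameter as `intercept + slope * d + N(0, sd * noise_scale)`. The
#' default noise levels are calibrated so the planted population Spearman
#' correlation between stance time and the MSFC-4 composite is about -0.6.
#' All magnitudes are plausible synthetic values, not fitted to any cohort.
#'
#' @param noise_scale multiplies every between-subject noise sd; 0 gives
#'   noise-free monotone maps (all feature-disability Spearman correlations
#'   exactly +/-1).
#' @return a named list of `c(intercept, slope, sd)` triplets plus
#'   `noise_scale`.
#' @export
effect_config <- function(noise_scale = 1) {
  list(
    noise_scale = noise_scale,
    stride_time_s   = c(0.95, 0.45, 0.12),  # stance = 0.55 + 0.35 d
    stance_frac     = c(0.55 / 0.95, NA, NA),  # derived, see below
    turn_peak_deg_s = c(220, -120, 10),
    sway_A_ml_mm    = c(1.0, 6, 0.5),
    sway_A_ap_mm    = c(1.5, 6, 0.5),
    rem_frac        = c(0.25, -0.10, 0.02),
    leg_rate_h      = c(2, 8, 0.5),
    idle_frac       = c(0.40, 0.30, 0.03),
    pvt_delay_ms    = c(250, 150, 15),
    hrv_rmssd_ms    = c(45, -25, 4),
    t25fw_s         = c(4.5, 5, 1.9),
    nhpt_s          = c(18, 14, 5.6),
    sdmt_correct    = c(62, -25, 9.6),
    lcva_correct    = c(58, -18, 8.0)
  )
}

eff <- function(cfg, name, d) {
  v <- cfg[[name]]
  v[1] + v[2] * d + rnorm(length(d), 0, v[3] * cfg$noise_scale)
}

#' Draw subject profiles for a synthetic cohort
#'
#' Latent disability `d ~ Uniform(0, 1)`; EDSS is derived from `d` by
#' quantile mapping onto the half-step grid 1.0-6.5 (keeping EDSS ordinal
#' and in the cohort's range); true gait, turn, sway, sleep, activity and
#' fatigue parameters follow [effect_config()].
#'
#' @param n_subjects number of subjects (>= 3).
#' @param effect an [effect_config()].
#' @param seed RNG seed.
#' @return tibble of per-subject true parameters (one row per subject).
#' @export
subject_profiles <- function(n_subjects = 23, effect = effect_config(),
                             seed = 1) {
  if (n_subjects < 3) validation_error("need at least 3 subjects")
  set.seed(seed)
  d <- runif(n_subjects)
  grid <- seq(1, 6.5, by = 0.5)
  edss <- grid[pmin(length(grid), floor(d * length(grid)) + 1L)]
  stride <- eff(effect, "stride_time_s", d)
  stance <- 0.55 + 0.35 * d +
    (stride - (0.95 + 0.45 * d)) * (0.35 / 0.45)  # stance noise ~ sd 0.093
  stance <- pmin(stance, stride - 0.15)  # keep a physical swing phase
  tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(n_subjects)),
    d = d,
    edss = edss,
    stride_time_s = stride,
    stance_time_s = stance,
    swing_time_s = stride - stance,
    stance_fraction = stance / stride,
    stride_rate_hz = 1 / stride,
    cadence_spm = 120 / stride,
    turn_peak_deg_s = pmax(eff(effect, "turn_peak_deg_s", d), 40),
    sway_A_ml_mm = pmax(eff(effect, "sway_A_ml_mm", d), 0.2),
    sway_A_ap_mm = pmax(eff(effect, "sway_A_ap_mm", d), 0.2),
    rem_frac = pmin(pmax(eff(effect, "rem_frac", d), 0.05), 0.45),
    leg_rate_h = pmax(eff(effect, "leg_rate_h", d), 0),
    idle_frac = pmin(pmax(eff(effect, "idle_frac", d), 0.05), 0.9),
    pvt_delay_ms = pmax(eff(effect, "pvt_delay_ms", d), 150),
    hrv_rmssd_ms = pmax(eff(effect, "hrv_rmssd_ms", d), 8)
  )
}

#' Clinical scores of a synthetic cohort
#'
#' Raw MSFC-4 subtest scores generated from the latent disability with the
#' configured noise: timed tests (T25FW, 9HPT) increase with disability,
#' correct-response counts (SDMT, LCVA) decrease.
#'
#' @param profiles output of [subject_profiles()].
#' @param effect the same [effect_config()] used for the profiles.
#' @param visit visit index recorded in the table.
#' @param seed RNG seed.
#' @return clinical tibble in the [read_clinical_table()] schema.
#' @export
simulate_clinical_scores <- function(profiles, effect = effect_config(),
                                     visit = 2, seed = 1) {
  set.seed(seed)
  d <- profiles$d
  tibble::tibble(
    subject = profiles$subject_id,
    visit = visit,
    edss = profiles$edss,
    t25fw_s = pmax(eff(effect, "t25fw_s", d), 2.5),
    nhpt_s = pmax(eff(effect, "nhpt_s", d), 10),
    sdmt_correct = round(pmax(eff(effect, "sdmt_correct", d), 5)),
    lcva_correct = round(pmax(eff(effect, "lcva_correct", d), 5))
  )
}

#' Simulate one subject's in-clinic session
#'
#' Builds the structured-session signals for one subject: ankle sagittal
#' gyro gait bouts inside three TUG trials and a walk test, a chest (and
#' ankle) yaw 180-degree turn in each TUG, a 30-s sway track for the
#' balance window, a short resting IBI stretch, and a 3-minute PVT log -
#' plus the session annotation and the full ground truth.
#'
#' @param profile one row of [subject_profiles()].
#' @param fs sample rate of the simulated IMU streams, Hz.
#' @param walk_s duration of the walk test (nominally 120 s; tests may
#'   scale it down).
#' @param noise_sd additive IMU noise, deg/s.
#' @param seed RNG seed.
#' @return list: `annotation`, `recordings` (left_ankle, right_ankle,
#'   chest `ms_recording`s), `sway` (displacement track + truth), `ibi`,
#'   `pvt` (`ms_pvt_log`), `truth` (gait strides, turns, PVT mean).
#' @export
simulate_clinic_session <- function(profile, fs = 50, walk_s = 120,
                                    noise_sd = 3, seed = 1) {
  stopifnot(nrow(profile) == 1)
  sr <- profile$stride_rate_hz
  sfr <- profile$stance_fraction
  tug_walk_s <- max(8, 4 * 2 / sr)  # enough strides per TUG leg
  tug_s <- tug_walk_s + 4           # walk out, turn, walk back
  # task schedule (device clock, seconds)
  t_stand <- c(0, 10); t_bal <- c(10, 40); t_sit <- c(40, 50)
  tug_starts <- 50 + (0:2) * (tug_s + 5)
  t_walk <- c(max(tug_starts) + tug_s + 5,
              max(tug_starts) + tug_s + 5 + walk_s)
  total_s <- t_walk[2] + 5
  ann <- session_annotation(
    dplyr::bind_rows(
      tibble::tibble(label = "stand", start_s = t_stand[1], end_s = t_stand[2]),
      tibble::tibble(label = "balance_30s", start_s = t_bal[1], end_s = t_bal[2]),
      tibble::tibble(label = "sit", start_s = t_sit[1], end_s = t_sit[2]),
      tibble::tibble(label = "tug", start_s = tug_starts,
                     end_s = tug_starts + tug_s, rep = 1:3),
      tibble::tibble(label = "walk_2min", start_s = t_walk[1], end_s = t_walk[2])),
    subject = profile$subject_id, device = "multi")

  t <- seq(0, total_s, by = 1 / fs)
  gl <- numeric(length(t)); gr <- numeric(length(t)); yaw <- numeric(length(t))
  strides <- list(); turns <- list()
  # src and dest share the sample rate; an integer index offset avoids
  # floating-point jitter on the time grid
  place <- function(dest, src_t, src_y, at) {
    idx <- round(at * fs) + round(src_t * fs) + 1L
    ok <- idx >= 1 & idx <= length(t)
    dest[idx[ok]] <- src_y[ok]
    dest
  }
  k <- 0
  for (j in seq_along(tug_starts)) {
    k <- k + 1
    gb <- simulate_gait_bout(sr, sfr, tug_walk_s, fs = fs, noise_sd = 0,
                             seed = derive_seed(seed, 11, j), start_s = 0.5)
    at <- tug_starts[j] + 1
    gl <- place(gl, gb$trace$t, gb$trace$gyro_left, at)
    gr <- place(gr, gb$trace$t, gb$trace$gyro_right, at)
    strides[[k]] <- dplyr::mutate(gb$truth, toe_off_t = .data$toe_off_t + at,
                                  heel_strike_t = .data$heel_strike_t + at,
                                  task = "tug", rep = j)
    # 180-degree turn mid-TUG at the subject's peak yaw velocity
    turn_T <- 2 * 180 / profile$turn_peak_deg_s
    tu <- simulate_turn(180, turn_T, fs = fs, noise_sd = 0,
                        seed = derive_seed(seed, 12, j), margin_s = 0)
    at_turn <- tug_starts[j] + 1 + tug_walk_s / 2
    yaw <- place(yaw, tu$trace$t, tu$trace$yaw, at_turn)
    turns[[j]] <- dplyr::mutate(tu$truth, start_s = .data$start_s + at_turn,
                                end_s = .data$end_s + at_turn, rep = j)
  }
  gbw <- simulate_gait_bout(sr, sfr, walk_s - 1, fs = fs, noise_sd = 0,
                            seed = derive_seed(seed, 13), start_s = 0.5)
  gl <- place(gl, gbw$trace$t, gbw$trace$gyro_left, t_walk[1] + 0.5)
  gr <- place(gr, gbw$trace$t, gbw$trace$gyro_right, t_walk[1] + 0.5)
  strides[[k + 1]] <- dplyr::mutate(
    gbw$truth, toe_off_t = .data$toe_off_t + t_walk[1] + 0.5,
    heel_strike_t = .data$heel_strike_t + t_walk[1] + 0.5,
    task = "walk_2min", rep = NA_integer_)
  set.seed(derive_seed(seed, 14))
  if (noise_sd > 0) {
    gl <- gl + rnorm(length(t), 0, noise_sd)
    gr <- gr + rnorm(length(t), 0, noise_sd)
    yaw <- yaw + rnorm(length(t), 0, noise_sd)
  }
  zero <- rep(0, length(t))
  mk_rec <- function(gy_main, loc, yaw_axis = zero) {
    sensor_recording(
      tibble::tibble(t = t, ax = zero, ay = zero, az = zero + 9.81,
                     gx = zero, gy = gy_main, gz = yaw_axis),
      profile$subject_id, loc, fs)
  }
  recs <- list(
    left_ankle = mk_rec(gl, "left_ankle", yaw),
    right_ankle = mk_rec(gr, "right_ankle", yaw),
    chest = mk_rec(zero, "chest", yaw))
  sway <- simulate_sway_track("filtered_noise", profile$sway_A_ml_mm,
                              profile$sway_A_ap_mm, f_hz = 0.5,
                              duration_s = 30, fs = fs,
                              seed = derive_seed(seed, 15))
  sway$track$t <- sway$track$t + t_bal[1]
  ibi <- simulate_ibi_night(
    tibble::tibble(stage = "WAKE", minutes = 6),
    stage_params = list(WAKE = list(mean_ibi_ms = 800,
                                    rmssd_ms = profile$hrv_rmssd_ms)),
    seed = derive_seed(seed, 16))
  set.seed(derive_seed(seed, 17))
  n_ch <- 20
  fsx <- runif(n_ch) < 0.05
  delays <- pmax(rnorm(n_ch, profile$pvt_delay_ms, 40), 120)
  pvt <- pvt_log(tibble::tibble(
    subject = profile$subject_id, session_t = 0, challenge_idx = seq_len(n_ch),
    delay_ms = ifelse(fsx, 0, delays), false_start = fsx))
  list(annotation = ann, recordings = recs, sway = sway, ibi = ibi$ibi,
       truth = list(strides = dplyr::bind_rows(strides),
                    turns = dplyr::bind_rows(turns),
                    sway = sway$truth,
                    pvt_mean_delay_ms = mean(delays[!fsx])),
       pvt = pvt)
}

#' Simulate one condensed free-living day
#'
#' Emits a wrist accelerometer stream and an ankle gyro stream for a
#' monitored window of `day_minutes`, following a planted schedule of idle,
#' walking and other activity whose idle fraction comes from the subject
#' profile. Walking segments carry a wrist oscillation at the subject's
#' stride rate plus the ankle swing-pulse gait signal; idle segments are
#' near-still; "other" segments are aperiodic moderate motion.
#'
#' @param profile one row of [subject_profiles()].
#' @param day day index (enters the derived seed, so days differ but are
#'   reproducible).
#' @param day_minutes length of the monitored window, minutes.
#' @param fs sample rate, Hz.
#' @param seed cohort master seed.
#' @param walk_frac fraction of the day spent walking.
#' @param day_stance_sd day-to-day wobble of the subject's stance time, s.
#' @return list: `wrist`, `ankle` (`ms_recording`s), `truth` (schedule
#'   tibble with per-segment labels and the day's true stance time).
#' @export
simulate_freeliving_day <- function(profile, day, day_minutes = 30, fs = 20,
                                    seed = 1, walk_frac = 0.2,
                                    day_stance_sd = 0.02) {
  day_s <- day_minutes * 60
  subj_key <- suppressWarnings(as.integer(gsub("\\D", "", profile$subject_id)))
  if (is.na(subj_key)) subj_key <- sum(utf8ToInt(profile$subject_id))
  set.seed(derive_seed(seed, 31, day, subj_key))
  # day-level gait parameters wobble around the subject's true values
  stance_day <- max(0.3, profile$stance_time_s + rnorm(1, 0, day_stance_sd))
  stride_day <- max(stance_day + 0.2, profile$stride_time_s + rnorm(1, 0, 0.02))
  # segment schedule: idle / walk / other blocks of 1-5 min until full
  labels <- c(); durs <- c()
  idle_target <- profile$idle_frac
  other_target <- max(0, 1 - idle_target - walk_frac)
  remaining <- day_s
  while (remaining > 0) {
    lab <- sample(c("idle", "walking", "other"), 1,
                  prob = c(idle_target, walk_frac, other_target))
    dur <- min(remaining, round(runif(1, 60, 300)))
    labels <- c(labels, lab); durs <- c(durs, dur)
    remaining <- remaining - dur
  }
  starts <- cumsum(c(0, head(durs, -1)))
  sched <- tibble::tibble(label = labels, start_s = starts,
                          end_s = starts + durs)
  t <- seq(0, day_s - 1 / fs, by = 1 / fs)
  n <- length(t)
  wx <- rnorm(n, 0, 0.02); wy <- rnorm(n, 0, 0.02)
  wz <- 9.81 + rnorm(n, 0, 0.02)
  ankle_gy <- rnorm(n, 0, 1)
  stride_rate_day <- 1 / stride_day
  strides <- list()
  for (i in seq_len(nrow(sched))) {
    idx <- t >= sched$start_s[i] & t < sched$end_s[i]
    if (sched$label[i] == "walking") {
      seg_dur <- sched$end_s[i] - sched$start_s[i]
      if (seg_dur < 2 * stride_day) { sched$label[i] <- "other"; next }
      # vertical bounce at the stride rate dominates the wrist magnitude
      wz[idx] <- wz[idx] +
        2 * sin(2 * pi * stride_rate_day * (t[idx] - sched$start_s[i]))
      wx[idx] <- wx[idx] +
        0.8 * sin(2 * pi * stride_rate_day * (t[idx] - sched$start_s[i]))
      gb <- simulate_gait_bout(stride_rate_day, stance_day / stride_day,
                               seg_dur - 1 / fs, fs = fs, noise_sd = 0,
                               seed = derive_seed(seed, 32, day, subj_key * 1000 + i),
                               start_s = 0.3)
      ii <- which(idx)[seq_along(gb$trace$t)]
      ankle_gy[ii] <- ankle_gy[ii] + gb$trace$gyro_left
      strides[[length(strides) + 1]] <- dplyr::mutate(
        gb$truth, toe_off_t = .data$toe_off_t + sched$start_s[i],
        heel_strike_t = .data$heel_strike_t + sched$start_s[i])
    } else if (sched$label[i] == "other") {
      # aperiodic moderate motion: low-passed noise, no dominant stride band
      wx[idx] <- wx[idx] + filtfilt_pad(rnorm(sum(idx), 0, 3), fs, 5, "low")
      wz[idx] <- wz[idx] + filtfilt_pad(rnorm(sum(idx), 0, 2), fs, 5, "low")
    }
  }
  mk <- function(ax, ay, az, gy, loc) {
    sensor_recording(tibble::tibble(t = t, ax = ax, ay = ay, az = az,
                                    gx = 0, gy = gy, gz = 0),
                     profile$subject_id, loc, fs)
  }
  list(wrist = mk(wx, wy, wz, rep(0, n), "left_wrist"),
       ankle = mk(rnorm(n, 0, 0.02), rnorm(n, 0, 0.02),
                  9.81 + rnorm(n, 0, 0.02), ankle_gy, "left_ankle"),
       truth = list(schedule = sched, stance_time_s = stance_day,
                    strides = if (length(strides)) dplyr::bind_rows(strides)
                              else NULL))
}

#' Simulate a full synthetic cohort
#'
#' Draws subject profiles, clinical scores and per-subject in-clinic
#' sessions. Free-living days are not materialised here (a full cohort of
#' day-long streams would be enormous); they are generated on demand,
#' deterministically, with [simulate_freeliving_day()] using the same
#' master seed.
#'
#' @param n_subjects cohort size (default 23, the analysed cohort size).
#' @param effect an [effect_config()].
#' @param seed master RNG seed.
#' @param fs in-clinic IMU sample rate, Hz.
#' @param walk_s walk-test duration, s.
#' @param clinic_noise_sd in-clinic IMU noise, deg/s.
#' @param sessions if `FALSE`, skip signal synthesis and return profiles +
#'   clinical scores only (fast path for statistics-level studies).
#' @return list: `profiles`, `clinical`, `sessions` (per-subject list),
#'   `seed`.
#' @export
simulate_cohort <- function(n_subjects = 23, effect = effect_config(),
                            seed = 1, fs = 50, walk_s = 120,
                            clinic_noise_sd = 3, sessions = TRUE) {
  profiles <- subject_profiles(n_subjects, effect, seed = derive_seed(seed, 1))
  clinical <- simulate_clinical_scores(profiles, effect,
                                       seed = derive_seed(seed, 2))
  sess <- NULL
  if (sessions) {
    sess <- lapply(seq_len(n_subjects), function(i) {
      simulate_clinic_session(profiles[i, ], fs = fs, walk_s = walk_s,
                              noise_sd = clinic_noise_sd,
                              seed = derive_seed(seed, 3, i))
    })
    names(sess) <- profiles$subject_id
  }
  list(profiles = profiles, clinical = clinical, sessions = sess, seed = seed)
}

#' Write a cohort to disk in the package's on-disk formats
#'
#' Sensor CSVs, annotation JSONs, the clinical CSV and PVT logs, plus a
#' manifest JSON listing every emitted file and a ground-truth sidecar
#' JSON per subject.
#'
#' @param cohort output of [simulate_cohort()] (with sessions).
#' @param dir output directory (created if needed).
#' @return manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  add <- function(p) files[[length(files) + 1]] <<- p
  p <- file.path(dir, "clinical.csv")
  write_clinical_table(cohort$clinical, p); add(p)
  for (sid in names(cohort$sessions)) {
    s <- cohort$sessions[[sid]]
    for (loc in names(s$recordings)) {
      p <- file.path(dir, sprintf("%s_%s.csv", sid, loc))
      write_sensor_csv(s$recordings[[loc]], p); add(p)
    }
    p <- file.path(dir, sprintf("%s_annotation.json", sid))
    write_annotations(s$annotation, p); add(p)
    p <- file.path(dir, sprintf("%s_pvt.csv", sid))
    write_pvt_log(s$pvt, p); add(p)
    p <- file.path(dir, sprintf("%s_truth.json", sid))
    jsonlite::write_json(lapply(s$truth, function(x)
      if (is.data.frame(x)) as.data.frame(x) else x),
      p, auto_unbox = TRUE, digits = NA); add(p)
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(n_subjects = nrow(cohort$profiles), seed = cohort$seed,
         files = unlist(files)),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
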