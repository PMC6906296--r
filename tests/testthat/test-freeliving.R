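walking_recording <- function(duration_s, stride_hz = 0.9, fs = 20,
                              seed = 1) {
  set.seed(seed)
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  n <- length(t)
  sensor_recording(
    tibble::tibble(t = t, ax = 0.8 * sin(2 * pi * stride_hz * t) +
                     rnorm(n, 0, 0.05),
                   ay = rnorm(n, 0, 0.05),
                   az = 9.81 + 2 * sin(2 * pi * stride_hz * t) +
                     rnorm(n, 0, 0.05),
                   gx = 0, gy = 0, gz = 0),
    "S01", "left_wrist", fs)
}

test_that("window featurisation has the documented shape and spectra", {
  # 10 s of data, 5-s windows -> 2 windows
  rec <- still_recording(10, fs = 20)
  f <- extract_windows(rec)
  expect_equal(nrow(f), 2)
  expect_lt(max(f$accel_var), 1e-10)
  expect_equal(f$dom_freq_hz, c(0, 0))
  # pure 1.8 Hz oscillation localises to the FFT bin resolution (0.2 Hz)
  t <- seq(0, 20 - 1 / 20, by = 1 / 20)
  rec2 <- sensor_recording(
    tibble::tibble(t = t, ax = 0, ay = 0,
                   az = 9.81 + 1.5 * sin(2 * pi * 1.8 * t),
                   gx = 0, gy = 0, gz = 0), "S01", "left_wrist", 20)
  f2 <- extract_windows(rec2)
  expect_true(all(abs(f2$dom_freq_hz - 1.8) <= 0.2 + 1e-9))
  expect_error(extract_windows(still_recording(3, fs = 20)),
               class = "mswear_validation_error")
})

test_that("threshold classifier recovers a planted schedule", {
  fs <- 20
  # planted minutes: idle 30, walking 6, other 12 (scaled-down day)
  blocks <- tibble::tibble(
    label = c("idle", "walking", "idle", "other", "walking", "idle",
              "other", "idle"),
    minutes = c(8, 3, 7, 6, 3, 7, 6, 8))
  segs <- list(); t0 <- 0
  for (i in seq_len(nrow(blocks))) {
    d <- blocks$minutes[i] * 60
    t <- seq(0, d - 1 / fs, by = 1 / fs)
    n <- length(t)
    set.seed(i)
    seg <- switch(blocks$label[i],
      idle = tibble::tibble(ax = rnorm(n, 0, 0.02), ay = rnorm(n, 0, 0.02),
                            az = 9.81 + rnorm(n, 0, 0.02)),
      walking = tibble::tibble(ax = 0.8 * sin(2 * pi * 0.9 * t),
                               ay = rnorm(n, 0, 0.05),
                               az = 9.81 + 2 * sin(2 * pi * 0.9 * t) +
                                 rnorm(n, 0, 0.05)),
      other = tibble::tibble(
        ax = filtfilt_sig(rnorm(n, 0, 3), fs),
        ay = rnorm(n, 0, 0.1),
        az = 9.81 + filtfilt_sig(rnorm(n, 0, 2), fs)))
    seg$t <- t + t0
    segs[[i]] <- seg
    t0 <- t0 + d
  }
  df <- dplyr::bind_rows(segs)
  df$gx <- 0; df$gy <- 0; df$gz <- 0
  rec <- sensor_recording(df[, c("t", "ax", "ay", "az", "gx", "gy", "gz")],
                          "S01", "left_wrist", fs)
  feats <- extract_windows(rec)
  bouts <- classify_activity(feats)
  idle_min <- sum((bouts$end_s - bouts$start_s)[bouts$label == "idle"]) / 60
  expect_lt(abs(idle_min - 30), 5)
  # walking windows recovered
  wtruth <- rep(blocks$label, blocks$minutes * 60 / 5)
  west <- sapply(feats$start_s, function(tt)
    bouts$label[which(tt >= bouts$start_s - 1e-9 & tt < bouts$end_s)[1]])
  ww <- wtruth == "walking"
  expect_gte(mean(west[ww] == "walking"), 0.95)
  # zero-motion input is idle
  still <- extract_windows(still_recording(60, fs = fs, noise_sd = 0.01))
  bs <- classify_activity(still)
  expect_equal(unique(bs$label), "idle")
})

test_that("classifier window accuracy is at least 90% across 20 seeds", {
  prof <- subject_profiles(5, seed = 8)
  accs <- numeric(0)
  for (s in 1:20) {
    sim <- simulate_freeliving_day(prof[1 + s %% 5, ], s, day_minutes = 15,
                                   seed = s)
    feats <- extract_windows(sim$wrist)
    bouts <- classify_activity(feats)
    truth <- sapply(feats$start_s + 2.5, function(tt) {
      sc <- sim$truth$schedule
      sc$label[which(tt >= sc$start_s & tt < sc$end_s)[1]]
    })
    est <- sapply(feats$start_s, function(tt)
      bouts$label[which(tt >= bouts$start_s - 1e-9 & tt < bouts$end_s)[1]])
    accs <- c(accs, mean(est == truth, na.rm = TRUE))
  }
  expect_true(all(accs >= 0.9))
})

test_that("bouts tile the monitored time without overlap", {
  prof <- subject_profiles(3, seed = 8)
  sim <- simulate_freeliving_day(prof[1, ], 1, day_minutes = 15, seed = 4)
  feats <- extract_windows(sim$wrist)
  bouts <- classify_activity(feats)
  expect_equal(sum(bouts$end_s - bouts$start_s),
               max(feats$end_s) - min(feats$start_s))
  expect_true(all(bouts$start_s[-1] >= bouts$end_s[-nrow(bouts)] - 1e-9))
})

test_that("walking-bout gait analysis recovers the planted stance time", {
  fs <- 20
  prof <- subject_profiles(3, seed = 8)
  sim <- simulate_freeliving_day(prof[2, ], 3, day_minutes = 20, seed = 5)
  feats <- extract_windows(sim$wrist)
  bouts <- classify_activity(feats)
  wb <- analyze_walking_bouts(list(ankle = sim$ankle), bouts)
  day <- daily_features(bouts, wb$strides, feats, day = 3)
  # this seeded layout plants walking segments
  expect_gt(sum(sim$truth$schedule$label == "walking"), 0)
  expect_true(day$gait_valid)
  expect_lt(abs(day$median_stance_s - sim$truth$stance_time_s), 0.03)
  expect_lte(day$idle_minutes, day$worn_hours * 60 + 1e-9)
  # a day with no walking carries no gait medians
  none <- daily_features(bouts[bouts$label != "walking", ],
                         wb$strides[0, ], feats, day = 1)
  expect_false(none$gait_valid)
  expect_true(is.na(none$median_stance_s))
})

test_that("compliance rules assign the documented groups", {
  mk <- function(subject, pct) tibble::tibble(
    subject = subject, week = seq_along(pct), worn_hours = pct / 100 * 70)
  weekly <- dplyr::bind_rows(
    mk("full", rep(100, 8)),
    mk("barely", rep(10, 8)),
    mk("fading", c(90, 85, 70, 60, 55, 50, 45, 40)))
  cr <- compliance(weekly, target_hours = 70)
  expect_equal(cr$group[cr$subject == "full"], "high")
  expect_equal(cr$group[cr$subject == "barely"], "low")
  expect_equal(cr$group[cr$subject == "fading"], "declining")
  expect_error(compliance(weekly, target_hours = 0),
               class = "mswear_validation_error")
})
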