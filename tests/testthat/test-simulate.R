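test_that("gait bout truth matches the stride schedule by construction", {
  gb <- simulate_gait_bout(1, 0.6, 10, fs = 100, seed = 1)
  expect_true(all(abs(gb$truth$stance_time_s - 0.6) < 1e-12))
  expect_true(all(abs(gb$truth$swing_time_s - 0.4) < 1e-12))
  # 10 s at 1 stride/s over two feet: 20 swing pulses, counted by an
  # independent enumeration of the event schedule
  expect_equal(nrow(gb$truth), count_swing_pulses(1, 0.6, 10))
  expect_equal(nrow(gb$truth), 20)
  # determinism under seed
  gb2 <- simulate_gait_bout(1, 0.6, 10, fs = 100, seed = 1, noise_sd = 5)
  gb3 <- simulate_gait_bout(1, 0.6, 10, fs = 100, seed = 1, noise_sd = 5)
  expect_identical(gb2$trace, gb3$trace)
  expect_error(simulate_gait_bout(1, 0.6, 10, fs = 15),
               class = "mswear_validation_error")
  expect_error(simulate_gait_bout(1, 1.2, 10), class = "mswear_validation_error")
})

test_that("turn pulse has the analytic raised-cosine properties", {
  tu <- simulate_turn(180, 2, fs = 100)
  expect_equal(tu$truth$peak_deg_s, 180)
  expect_equal(tu$truth$mean_deg_s, 90)
  expect_equal(max(tu$trace$yaw), 180, tolerance = 1e-3)
  # trapezoid quadrature of the emitted trace recovers the angle
  ang <- sum(diff(tu$trace$t) *
               (tu$trace$yaw[-1] + tu$trace$yaw[-nrow(tu$trace)]) / 2)
  expect_lt(abs(ang - 180), 0.2)
  # zero angle gives an all-zero trace
  z <- simulate_turn(0, 2, fs = 100)
  expect_true(all(z$trace$yaw == 0))
  expect_error(simulate_turn(90, 0), class = "mswear_validation_error")
})

test_that("sway track models have their analytic / deterministic contracts", {
  sw <- simulate_sway_track("sinusoid", A_ml_mm = 2, A_ap_mm = 1,
                            f_hz = 0.5, duration_s = 30, fs = 100)
  expect_equal(sw$truth$path_ml_mm, 120)  # 4 A f T
  expect_equal(sw$truth$range_ml_mm, 4)
  # emitted track agrees with the analytic path length
  expect_equal(sum(abs(diff(sw$track$ml_mm))), 120, tolerance = 0.01)
  z <- simulate_sway_track("sinusoid", A_ml_mm = 0, A_ap_mm = 1)
  expect_equal(sum(abs(diff(z$track$ml_mm))), 0)
  n1 <- simulate_sway_track("filtered_noise", 2, 2, seed = 9)
  n2 <- simulate_sway_track("filtered_noise", 2, 2, seed = 9)
  expect_identical(n1$track, n2$track)
  expect_error(simulate_sway_track("sinusoid", A_ml_mm = -1),
               class = "mswear_validation_error")
})

test_that("night generator plants the scheduled REM fraction", {
  all_nrem <- simulate_ibi_night(tibble::tibble(stage = "NREM", minutes = 400))
  expect_equal(all_nrem$truth$rem_percent, 0)
  mixed <- simulate_ibi_night(
    tibble::tibble(stage = c("REM", "NREM"), minutes = c(90, 310)))
  expect_equal(mixed$truth$rem_percent, 22.5)
  # degenerate constant-IBI parameters emit zero short-term variability
  const <- simulate_ibi_night(
    tibble::tibble(stage = "NREM", minutes = 30),
    stage_params = list(NREM = list(mean_ibi_ms = 800, rmssd_ms = 0)))
  expect_equal(sqrt(mean(diff(const$ibi$ibi_ms)^2)), 0)
  expect_error(simulate_ibi_night(tibble::tibble(stage = character(),
                                                 minutes = numeric())),
               class = "mswear_validation_error")
})

test_that("noise-free profiles are exactly monotone in disability", {
  prof <- subject_profiles(23, effect_config(noise_scale = 0), seed = 4)
  sgn <- function(x) as.numeric(suppressWarnings(
    cor(x, prof$d, method = "spearman")))
  expect_equal(sgn(prof$stance_time_s), 1)     # stance lengthens
  expect_equal(sgn(prof$turn_peak_deg_s), -1)  # turns slow
  expect_equal(sgn(prof$sway_A_ml_mm), 1)      # sway grows
  expect_equal(sgn(prof$idle_frac), 1)         # more idle time
  expect_equal(sgn(prof$rem_frac), -1)         # less REM
  expect_equal(sgn(prof$pvt_delay_ms), 1)      # slower reactions
  expect_true(all(prof$edss %in% seq(1, 6.5, 0.5)))
})

test_that("default noise plants the intended stance-composite effect size", {
  # Monte-Carlo against the generator's closed-form plan: the population
  # Spearman correlation between true stance time and the MSFC-4
  # composite is about -0.6 under default noise
  rhos <- vapply(1:200, function(s) {
    coh <- simulate_cohort(23, seed = s, sessions = FALSE)
    sc <- msfc4_scores(coh$clinical)
    as.numeric(spearman_rho(coh$profiles$stance_time_s,
                            sc$msfc4_composite))
  }, numeric(1))
  expect_lt(abs(mean(rhos) - (-0.6)), 0.1)
})

test_that("cohort simulation is deterministic under seed", {
  c1 <- simulate_cohort(4, seed = 11, fs = 40, walk_s = 15)
  c2 <- simulate_cohort(4, seed = 11, fs = 40, walk_s = 15)
  expect_identical(c1$profiles, c2$profiles)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$sessions[[2]]$recordings$chest,
                   c2$sessions[[2]]$recordings$chest)
  expect_error(simulate_cohort(2), class = "mswear_validation_error")
})

test_that("written cohort round trips through the on-disk formats", {
  coh <- simulate_cohort(3, seed = 2, fs = 40, walk_s = 15)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(coh, dir)
  expect_true(file.exists(manifest))
  listed <- jsonlite::read_json(manifest, simplifyVector = TRUE)$files
  expect_true(all(file.exists(listed)))
  back <- read_sensor_csv(file.path(dir, "S01_left_ankle.csv"))
  orig <- coh$sessions$S01$recordings$left_ankle
  expect_equal(back$gy, signif(orig$gy, 6))
  cl <- read_clinical_table(file.path(dir, "clinical.csv"))
  expect_equal(cl$edss, coh$clinical$edss)
})
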