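ibi_series <- function(ibis_ms, t0 = 0) {
  tibble::tibble(t = t0 + cumsum(c(0, head(ibis_ms, -1))) / 1000,
                 ibi_ms = ibis_ms)
}

test_that("HRV epoch features match their closed forms", {
  # constant IBI: zero SDNN and RMSSD
  ep <- hrv_epochs(ibi_series(rep(800, 400)))
  expect_equal(ep$sdnn_ms[1], 0)
  expect_equal(ep$rmssd_ms[1], 0)
  # alternating 800/820: every successive difference is +/-20
  alt <- hrv_epochs(ibi_series(rep(c(800, 820), 200)))
  expect_equal(alt$rmssd_ms[1], 20, tolerance = 1e-9)
  # a 5000 ms artifact is removed by the ectopic filter
  with_art <- c(rep(800, 100), 5000, rep(800, 100))
  ep2 <- hrv_epochs(ibi_series(with_art))
  expect_equal(sum(ep2$n_beats), 200)
  expect_equal(ep2$rmssd_ms[1], 0)
  # shift invariance: adding a constant to all IBIs changes nothing
  base <- rep(c(780, 800, 830), 100)
  e1 <- hrv_epochs(ibi_series(base))
  e2 <- hrv_epochs(ibi_series(base + 100))
  expect_equal(e1$sdnn_ms, e2$sdnn_ms)
  expect_equal(e1$rmssd_ms, e2$rmssd_ms)
})

test_that("REM estimation recovers planted stage structure", {
  # single-class night
  nrem <- simulate_ibi_night(tibble::tibble(stage = "NREM", minutes = 400),
                             seed = 3)
  est0 <- estimate_rem_percent(hrv_epochs(nrem$ibi))
  expect_lte(est0$rem_percent, 5)
  # planted 22.5% REM with default stage separation
  mixed <- simulate_ibi_night(
    tibble::tibble(stage = c("NREM", "REM", "NREM", "REM", "NREM"),
                   minutes = c(120, 40, 150, 50, 40)), seed = 7)
  est <- estimate_rem_percent(hrv_epochs(mixed$ibi))
  expect_lt(abs(est$rem_percent - mixed$truth$rem_percent), 5)
  # degenerate threshold zero: everything is REM
  est100 <- estimate_rem_percent(hrv_epochs(mixed$ibi), threshold_ms = 0)
  expect_equal(est100$rem_percent, 100)
  # too few epochs
  tiny <- hrv_epochs(ibi_series(rep(800, 100)))
  expect_error(estimate_rem_percent(tiny), class = "mswear_validation_error")
})

test_that("REM recovery stays within 5 points across seeds", {
  errs <- vapply(1:15, function(s) {
    sch <- tibble::tibble(stage = c("NREM", "REM", "NREM", "REM", "NREM"),
                          minutes = c(90, 30, 120, 60, 60))
    sim <- simulate_ibi_night(sch, seed = s)
    est <- estimate_rem_percent(hrv_epochs(sim$ibi))
    abs(est$rem_percent - sim$truth$rem_percent)
  }, numeric(1))
  expect_lt(max(errs), 5)
})

test_that("leg movements are counted with the refractory rule", {
  fs <- 20
  mk_night <- function(move_starts, hours = 6) {
    t <- seq(0, hours * 3600 - 1 / fs, by = 1 / fs)
    az <- rep(9.81, length(t))
    for (m in move_starts) {
      idx <- t >= m & t < m + 1
      az[idx] <- az[idx] + 0.5 * sin(2 * pi * 3 * (t[idx] - m))
    }
    sensor_recording(tibble::tibble(t = t, ax = 0, ay = 0, az = az,
                                    gx = 0, gy = 0, gz = 0),
                     "S01", "left_ankle", fs)
  }
  # 12 well-separated movements in 6 h -> 2.0 per hour
  rec <- mk_night(seq(600, 20000, length.out = 12))
  lm <- leg_movement_rate(rec)
  expect_equal(lm$n_events, 12)
  expect_equal(lm$rate_per_h, 2.0)
  # motionless night
  lm0 <- leg_movement_rate(mk_night(numeric(0)))
  expect_equal(lm0$rate_per_h, 0)
  # two movements 2 s apart merge under the 5-s refractory rule
  lm2 <- leg_movement_rate(mk_night(c(1000, 1002)))
  expect_equal(lm2$n_events, 1)
  expect_error(leg_movement_rate(mk_night(numeric(0), hours = 0.5)),
               class = "mswear_validation_error")
})

test_that("PVT features follow the first-k and false-start rules", {
  mk_log <- function(delays, fs_flags) pvt_log(tibble::tibble(
    subject = "S01", session_t = 0, challenge_idx = seq_along(delays),
    delay_ms = delays, false_start = fs_flags))
  f <- pvt_features(mk_log(c(300, 250, 350), rep(FALSE, 3)))
  expect_equal(f$mean_delay_total_ms, 300)
  expect_equal(f$mean_delay_first_1_ms, 300)
  expect_equal(f$mean_delay_first_3_ms, 300)
  # single challenge: every feature collapses to it
  f1 <- pvt_features(mk_log(200, FALSE))
  expect_equal(unlist(f1[1:5], use.names = FALSE), rep(200, 5))
  # a false start is skipped when counting the first k valid challenges
  f2 <- pvt_features(mk_log(c(400, 0, 300, 350, 250, 300),
                            c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)))
  expect_equal(f2$mean_delay_first_3_ms, 350)
  expect_equal(f2$n_false_starts, 1L)
  expect_error(pvt_features(mk_log(0, TRUE)),
               class = "mswear_validation_error")
})
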