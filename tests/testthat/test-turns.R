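test_that("constant-rate and raised-cosine turns match their analytics", {
  fs <- 100
  # constant 90 deg/s for 2 s between zero margins
  t <- seq(0, 4, by = 1 / fs)
  yaw <- ifelse(t >= 1 & t < 3, 90, 0)
  tu <- detect_turns(tibble::tibble(t = t, yaw = yaw), fs)
  expect_equal(nrow(tu), 1)
  expect_lt(abs(tu$angle_deg - 180), 1)
  # the zero-phase low-pass smears the step edges symmetrically, so the
  # detected span (to the 5 deg/s crossings) slightly exceeds the pulse
  expect_lt(abs(tu$duration_s - 2), 0.6)
  expect_equal(tu$peak_velocity_deg_s, 90)
  expect_lt(abs(tu$mean_velocity_deg_s - 90), 15)
  # raised cosine, 180 degrees over 2 s
  sim <- simulate_turn(180, 2, fs = fs)
  tu2 <- detect_turns(sim$trace, fs)
  expect_equal(nrow(tu2), 1)
  expect_lt(abs(tu2$peak_velocity_deg_s - 180), 2)
  expect_lt(abs(tu2$angle_deg - 180), 2)
})

test_that("sub-threshold yaw yields no turns and short input errors", {
  fs <- 50
  set.seed(2)
  quiet <- tibble::tibble(t = seq(0, 10, by = 1 / fs))
  quiet$yaw <- runif(nrow(quiet), -9, 9)
  expect_equal(nrow(detect_turns(quiet, fs)), 0)
  expect_error(detect_turns(rnorm(10), fs = 5),
               class = "mswear_validation_error")
})

test_that("detected angle matches raw-trace quadrature within 2 percent", {
  fs <- 100
  for (ang in c(90, 135, 180, 270)) {
    sim <- simulate_turn(ang, 1.5, fs = fs)
    tu <- detect_turns(sim$trace, fs)
    expect_equal(nrow(tu), 1)
    i <- sim$trace$t >= tu$start_s & sim$trace$t <= tu$end_s
    raw_int <- sum(diff(sim$trace$t[i]) *
                     (sim$trace$yaw[i][-1] + sim$trace$yaw[i][-sum(i)]) / 2)
    expect_lt(abs(tu$angle_deg - raw_int) / abs(raw_int), 0.02)
  }
})

test_that("planted TUG turns are found with perfect recall and precision", {
  fs <- 50
  hits <- 0; falses <- 0; total <- 0
  for (s in 1:50) {
    # three 180-degree turns in a quiet session, noise sd 10 deg/s
    t <- seq(0, 60, by = 1 / fs)
    yaw <- numeric(length(t))
    starts <- c(10, 30, 50)
    for (st in starts) {
      sim <- simulate_turn(180, 2, fs = fs, margin_s = 0)
      idx <- which(t >= st & t <= st + 2)[seq_along(sim$trace$yaw)]
      yaw[idx] <- sim$trace$yaw
    }
    set.seed(s)
    yaw <- yaw + rnorm(length(t), 0, 10)
    tu <- detect_turns(tibble::tibble(t = t, yaw = yaw), fs)
    total <- total + length(starts)
    for (st in starts) {
      hits <- hits + any(abs(tu$start_s - st) < 1.5)
    }
    falses <- falses + sum(!sapply(tu$start_s, function(x)
      any(abs(x - starts) < 1.5)))
  }
  expect_equal(hits, total)   # recall 1.0
  expect_equal(falses, 0)     # precision 1.0
})

test_that("turn summaries aggregate across turns as documented", {
  mk <- function(mean_v) tibble::tibble(
    start_s = 0, end_s = 2, duration_s = 2, angle_deg = mean_v * 2,
    peak_velocity_deg_s = mean_v * 2, mean_velocity_deg_s = mean_v,
    source_location = "chest")
  s3 <- summarize_turns(dplyr::bind_rows(mk(80), mk(100), mk(120)))
  expect_equal(s3$velocity_mean_deg_s, 100)
  expect_equal(s3$velocity_std_deg_s, sqrt(800 / 3), tolerance = 1e-6)
  # two identical turns: zero spread
  s2 <- summarize_turns(dplyr::bind_rows(mk(90), mk(90)))
  expect_equal(s2$velocity_std_deg_s, 0)
  # single turn: summary equals the turn
  s1 <- summarize_turns(mk(90))
  expect_equal(s1$velocity_mean_deg_s, 90)
  expect_equal(s1$mean_angle_deg, 180)
  # empty
  s0 <- summarize_turns(mk(90)[0, ])
  expect_equal(s0$n_turns, 0L)
})
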