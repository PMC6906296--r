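# Independent oracles, deliberately written without the package's own
# code paths.

# Benjamini-Hochberg by the textbook step-up definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- o[i]
    q[j] <- min(vapply(i:m, function(k) m * p[o[k]] / k, numeric(1)), 1)
  }
  q
}

# Midranks computed by counting, then the Pearson sum formula - no rank()
# or cor() involved.
midrank_oracle <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, numeric(1))
}

spearman_oracle <- function(x, y) {
  rx <- midrank_oracle(x)
  ry <- midrank_oracle(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# Enumerate the swing pulses a gait bout schedule implies, independently of
# the generator's own truth table.
count_swing_pulses <- function(stride_rate_hz, stance_fraction, duration_s,
                               start_s = 0) {
  stride_T <- 1 / stride_rate_hz
  swing_T <- (1 - stance_fraction) * stride_T
  n_left <- length(seq(start_s, duration_s - swing_T, by = stride_T))
  n_right <- length(seq(start_s + stride_T / 2, duration_s - swing_T,
                        by = stride_T))
  n_left + n_right
}

# zero-phase 5 Hz low-pass used to build aperiodic "other" activity
filtfilt_sig <- function(x, fs) {
  as.numeric(signal::filtfilt(signal::butter(2, 5 / (fs / 2), "low"), x))
}

# A still recording (gravity on z plus optional noise).
still_recording <- function(duration_s, fs = 20, noise_sd = 0, seed = 1,
                            subject = "T01", location = "left_wrist") {
  set.seed(seed)
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  n <- length(t)
  nz <- function() if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
  sensor_recording(
    tibble::tibble(t = t, ax = nz(), ay = nz(), az = 9.81 + nz(),
                   gx = 0, gy = 0, gz = 0),
    subject, location, fs)
}
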