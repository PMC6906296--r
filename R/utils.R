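# Internal numerical helpers shared by the extractors.

ms_abort <- function(msg, class) {
  rlang::abort(msg, class = c(class, "mswear_error"))
}

format_error <- function(msg) ms_abort(msg, "mswear_format_error")
validation_error <- function(msg) ms_abort(msg, "mswear_validation_error")

#' Zero-phase Butterworth filter with reflection padding
#'
#' Forward-backward (zero-phase) Butterworth filtering. The series is
#' reflection-padded at both ends before filtering so the filter transient
#' does not leak into the analysis window; `signal::filtfilt` alone assumes
#' zero signal outside the record.
#'
#' @param x numeric series, uniformly sampled.
#' @param fs sample rate in Hz.
#' @param cutoff_hz scalar (low/high) or length-2 vector (pass band), Hz.
#' @param type "low", "high" or "pass".
#' @param order Butterworth order of the one-way filter; applied twice, so
#'   the effective order is `2 * order`.
#' @return filtered series, same length as `x`.
#' @keywords internal
#' @noRd
filtfilt_pad <- function(x, fs, cutoff_hz, type = c("low", "high", "pass"),
                         order = 2) {
  type <- match.arg(type)
  n <- length(x)
  if (n < 8) return(x)
  w <- cutoff_hz / (fs / 2)
  if (any(w <= 0) || any(w >= 1)) {
    validation_error(sprintf(
      "filter cutoff %s Hz not realisable at sample rate %g Hz",
      paste(cutoff_hz, collapse = "-"), fs))
  }
  bf <- signal::butter(order, w, type)
  npad <- min(n - 1L, as.integer(ceiling(3 * fs / min(cutoff_hz))))
  xp <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  y <- signal::filtfilt(bf, xp)
  y[(npad + 1):(npad + n)]
}

# Cumulative trapezoid integral of y(t); result has the same length, first
# element 0.
cumtrapz <- function(t, y) {
  n <- length(y)
  if (n < 2) return(numeric(n))
  c(0, cumsum(diff(t) * (y[-1] + y[-n]) / 2))
}

trapz <- function(t, y) {
  n <- length(y)
  if (n < 2) return(0)
  sum(diff(t) * (y[-1] + y[-n]) / 2)
}

# Remove the least-squares line from y (drift control after integration).
detrend_linear <- function(t, y) {
  if (length(y) < 3) return(y - mean(y))
  fit <- stats::lm.fit(cbind(1, t), y)
  y - fit$fitted.values
}

# Refine an above-threshold crossing towards the signal baseline assuming a
# locally quadratic onset: for y ~ c * (t - t0)^2, t0 = t - 2 y / y'.
# `i` indexes the first sample above threshold adjacent to the crossing.
# An "onset" (rising edge) projects backwards in time, an "offset" (falling
# edge) forwards; the correction is clamped to max_shift_s and to the
# correct direction (a wrong-signed slope yields no correction).
refine_onset <- function(t, y, i, fs, direction = c("onset", "offset"),
                         max_shift_s = 0.08) {
  direction <- match.arg(direction)
  n <- length(y)
  if (i <= 1 || i >= n) return(t[i])
  slope <- (y[i + 1] - y[i - 1]) * fs / 2
  if (!is.finite(slope) || abs(slope) < 1e-9) return(t[i])
  shift <- -2 * y[i] / slope
  if (direction == "onset") {
    shift <- min(0, max(shift, -max_shift_s))
  } else {
    shift <- max(0, min(shift, max_shift_s))
  }
  t[i] + shift
}

# population (divide-by-n) standard deviation
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# rolling-majority smoothing of a logical/2-level label sequence, window 3
majority3 <- function(lab) {
  n <- length(lab)
  if (n < 3) return(lab)
  out <- lab
  for (i in 2:(n - 1)) {
    trio <- lab[(i - 1):(i + 1)]
    tt <- table(trio)
    out[i] <- names(tt)[which.max(tt)]
  }
  out
}

# Deterministic 32-bit sub-seed derived from a master seed and integer keys,
# kept strictly below 2^31. The multiplier is small enough that the
# intermediate product stays exactly representable in a double.
derive_seed <- function(seed, ...) {
  keys <- c(seed, ...)
  h <- 0
  for (k in keys) {
    h <- (h * 69069 + (as.numeric(k) %% 2147483647) + 12345) %% 2147483647
  }
  as.integer(h)
}
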