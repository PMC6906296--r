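# Postural sway from the 30-s standing-balance window. Two input paths:
# a 2-D displacement track (exact analytic tests) or horizontal
# acceleration (the realistic sensor path: gravity removal, band-pass,
# double trapezoid integration with a linear detrend after each
# integration for drift control). Path length is computed per axis - the
# reported quantity is the 1-D "sway distance left-right", not the 2-D
# trajectory length.

#' Default sway configuration
#' @param band_hz band-pass corners applied to horizontal acceleration, Hz.
#' @return named list of settings.
#' @export
sway_config <- function(band_hz = c(0.1, 2)) {
  list(band_hz = band_hz)
}

#' Compute postural sway metrics
#'
#' @param data either a displacement track (tibble `t`, `ml_mm`, `ap_mm`;
#'   uniform sampling required) or, with `input = "accel"`, an
#'   `ms_recording` whose accelerometer channels are in m/s^2.
#' @param input "displacement" or "accel".
#' @param window optional task-window row (`label` must be `balance_30s`);
#'   the data is sliced to it. At least 20 s of data is required.
#' @param fs sample rate; taken from the recording when `input = "accel"`.
#' @param config a [sway_config()].
#' @return one-row tibble: `sway_distance_ml_mm`, `sway_distance_ap_mm`
#'   (cumulative per-axis path length), `sway_displacement_ml_mm`,
#'   `sway_displacement_ap_mm` (max - min excursion), `duration_s`.
#' @export
compute_sway <- function(data, input = c("displacement", "accel"),
                         window = NULL, fs = NULL, config = sway_config()) {
  input <- match.arg(input)
  if (input == "displacement") {
    tr <- tibble::as_tibble(data)
    if (!is.null(window)) {
      check_balance_window(window)
      tr <- tr[tr$t >= window$start_s & tr$t < window$end_s, ]
    }
    if (nrow(tr) < 2) validation_error("empty balance window")
    dt <- diff(tr$t)
    if (max(dt) - min(dt) > 0.01 * stats::median(dt)) {
      validation_error("displacement input requires uniform sampling")
    }
    dur <- max(tr$t) - min(tr$t)
    if (dur < 20) validation_error("balance window shorter than 20 s")
    return(sway_metrics(tr$ml_mm, tr$ap_mm, dur))
  }
  rec <- data
  if (is.null(fs)) fs <- attr(rec, "sample_rate_hz")
  if (!is.null(window)) {
    check_balance_window(window)
    rec <- slice_window(rec, window)
  }
  if (nrow(rec) < 2) validation_error("empty balance window")
  dur <- max(rec$t) - min(rec$t)
  if (dur < 20) validation_error("balance window shorter than 20 s")
  acc <- cbind(rec$ax, rec$ay, rec$az)
  g <- colMeans(acc)
  ghat <- g / sqrt(sum(g^2))
  # horizontal device basis: ML along device x projected onto the
  # horizontal plane, AP completing the right-handed triad
  ex <- c(1, 0, 0)
  ml_axis <- ex - sum(ex * ghat) * ghat
  if (sqrt(sum(ml_axis^2)) < 1e-6) {   # device x parallel to gravity
    ey <- c(0, 1, 0)
    ml_axis <- ey - sum(ey * ghat) * ghat
  }
  ml_axis <- ml_axis / sqrt(sum(ml_axis^2))
  ap_axis <- c(ghat[2] * ml_axis[3] - ghat[3] * ml_axis[2],
               ghat[3] * ml_axis[1] - ghat[1] * ml_axis[3],
               ghat[1] * ml_axis[2] - ghat[2] * ml_axis[1])
  acc0 <- sweep(acc, 2, g)
  integ <- function(a) {
    af <- filtfilt_pad(a, fs, config$band_hz, "pass")
    v <- detrend_linear(rec$t, cumtrapz(rec$t, af))
    x <- detrend_linear(rec$t, cumtrapz(rec$t, v))
    x * 1000  # m -> mm
  }
  ml <- integ(as.numeric(acc0 %*% ml_axis))
  ap <- integ(as.numeric(acc0 %*% ap_axis))
  sway_metrics(ml, ap, dur)
}

check_balance_window <- function(window) {
  if (!identical(window$label, "balance_30s")) {
    validation_error("sway window must have label balance_30s")
  }
}

sway_metrics <- function(ml, ap, dur) {
  tibble::tibble(
    sway_distance_ml_mm = sum(abs(diff(ml))),
    sway_distance_ap_mm = sum(abs(diff(ap))),
    sway_displacement_ml_mm = if (length(ml)) max(ml) - min(ml) else 0,
    sway_displacement_ap_mm = if (length(ap)) max(ap) - min(ap) else 0,
    duration_s = dur)
}
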