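# broom-style accessors for the fitted result objects.

#' Tidy a correlation table
#'
#' @param x an `ms_cortab`.
#' @param ... unused.
#' @return a plain tibble, one row per feature x measure.
#' @export
tidy.ms_cortab <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' One-row summary of a correlation table
#'
#' @param x an `ms_cortab`.
#' @param ... unused.
#' @return tibble: number of tests, families, significant counts at
#'   q <= 0.05 / 0.01, and the strongest absolute correlation.
#' @export
glance.ms_cortab <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x),
    n_features = dplyr::n_distinct(x$feature),
    n_measures = dplyr::n_distinct(x$measure),
    n_sig_q05 = sum(x$sig_q05, na.rm = TRUE),
    n_sig_q01 = sum(x$sig_q01, na.rm = TRUE),
    max_abs_rho = max(abs(x$rho), na.rm = TRUE))
}

#' Tidy a variability curve
#' @param x an `ms_varcurve`.
#' @param ... unused.
#' @return per-subject tibble (cohort rows tagged `.cohort`).
#' @export
tidy.ms_varcurve <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' One-row summary of a variability curve
#' @param x an `ms_varcurve`.
#' @param ... unused.
#' @return tibble with the cohort curve endpoints and their ratio.
#' @export
glance.ms_varcurve <- function(x, ...) {
  coh <- x[x$subject == ".cohort", ]
  kmin <- min(coh$k); kmax <- max(coh$k)
  tibble::tibble(
    k_min = kmin, k_max = kmax,
    se_at_k_min = coh$se_median[coh$k == kmin],
    se_at_k_max = coh$se_median[coh$k == kmax],
    shrinkage = coh$se_median[coh$k == kmax] /
      coh$se_median[coh$k == kmin])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
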