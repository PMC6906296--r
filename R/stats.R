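# Clinical scoring (MSFC-4 z-scores and composite), Spearman correlation
# tables with Storey q-value FDR control, and the k-day median-variability
# analysis.

#' MSFC-4 z-scores and composite
#'
#' Standard MSFC convention: each subtest is z-scored against a reference
#' population; timed tests (T25FW, 9HPT) enter negated so that higher
#' always means better; the composite is the mean of the four subtest
#' z-scores. The default reference is this cohort at its baseline visit -
#' the classic MSFC choice when no external reference is named. The 9HPT
#' can alternatively enter as the z-score of 1/time (the classic rate
#' formulation) via `nhpt_mode = "inverse"`.
#'
#' @param clinical tibble in the [read_clinical_table()] schema (may hold
#'   several visits).
#' @param reference optional list with `means` and `sds`, each a named
#'   vector over `t25fw_s`, `nhpt_s` (or `nhpt_inv`), `sdmt_correct`,
#'   `lcva_correct`; derived from the baseline visit when `NULL`.
#' @param baseline_visit visit used for an internally derived reference
#'   (default: the smallest visit index present).
#' @param nhpt_mode "neg_z" (negated z of the time, symmetric with T25FW)
#'   or "inverse" (z of 1/time).
#' @return the clinical tibble with `z_25fw`, `z_9hpt`, `z_sdmt`,
#'   `z_lcva` and `msfc4_composite` columns appended.
#' @export
msfc4_scores <- function(clinical, reference = NULL, baseline_visit = NULL,
                         nhpt_mode = c("neg_z", "inverse")) {
  nhpt_mode <- match.arg(nhpt_mode)
  clinical <- tibble::as_tibble(clinical)
  nh <- function(x) if (nhpt_mode == "inverse") 1 / x else x
  vars <- c("t25fw_s", "nhpt_s", "sdmt_correct", "lcva_correct")
  if (is.null(reference)) {
    if (is.null(baseline_visit)) baseline_visit <- min(clinical$visit)
    base <- clinical[clinical$visit == baseline_visit, ]
    if (nrow(base) < 2) {
      validation_error("need >= 2 baseline subjects to derive a reference")
    }
    reference <- list(
      means = c(t25fw_s = mean(base$t25fw_s), nhpt_s = mean(nh(base$nhpt_s)),
                sdmt_correct = mean(base$sdmt_correct),
                lcva_correct = mean(base$lcva_correct)),
      sds = c(t25fw_s = sd(base$t25fw_s), nhpt_s = sd(nh(base$nhpt_s)),
              sdmt_correct = sd(base$sdmt_correct),
              lcva_correct = sd(base$lcva_correct)))
  }
  for (v in vars) {
    if (!is.finite(reference$sds[[v]]) || reference$sds[[v]] <= 0) {
      validation_error(sprintf("zero-variance reference for subscore %s", v))
    }
  }
  z <- function(x, v) (x - reference$means[[v]]) / reference$sds[[v]]
  out <- dplyr::mutate(
    clinical,
    z_25fw = -z(.data$t25fw_s, "t25fw_s"),
    z_9hpt = if (nhpt_mode == "inverse") z(1 / .data$nhpt_s, "nhpt_s")
             else -z(.data$nhpt_s, "nhpt_s"),
    z_sdmt = z(.data$sdmt_correct, "sdmt_correct"),
    z_lcva = z(.data$lcva_correct, "lcva_correct"))
  out$msfc4_composite <- rowMeans(cbind(out$z_25fw, out$z_9hpt,
                                        out$z_sdmt, out$z_lcva))
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks (average ranks on ties), computed from
#' the sum formulation. Incomplete pairs are dropped (pairwise deletion).
#'
#' @param x,y paired numeric vectors.
#' @return `rho` in \[-1, 1\], with attribute `n` (complete pairs used);
#'   `NA` (with a warning) when either variable is constant.
#' @export
spearman_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) validation_error("need at least 3 complete pairs")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sx <- sum((rx - mean(rx))^2)
  sy <- sum((ry - mean(ry))^2)
  if (sx == 0 || sy == 0) {
    rlang::warn("constant input: Spearman correlation undefined")
    rho <- NA_real_
  } else {
    rho <- sum((rx - mean(rx)) * (ry - mean(ry))) / sqrt(sx * sy)
  }
  attr(rho, "n") <- n
  rho
}

#' Two-sided p-value for a Spearman correlation (t approximation)
#'
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` referred to a t distribution
#' with `n - 2` degrees of freedom. `|rho| = 1` is handled as the limit
#' p -> 0.
#'
#' @param rho Spearman correlation (vectorised).
#' @param n number of pairs (>= 4).
#' @return two-sided p-value(s).
#' @export
spearman_pvalue <- function(rho, n) {
  if (any(n < 4)) validation_error("need n >= 4 for the t approximation")
  r2 <- pmin(rho^2, 1)
  tt <- ifelse(r2 >= 1, Inf, abs(rho) * sqrt((n - 2) / (1 - r2)))
  2 * stats::pt(-tt, n - 2)
}

#' Storey q-values
#'
#' The null proportion is estimated as
#' `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))` on the grid
#' `lambda = 0, 0.05, ..., 0.90`, extrapolated to `lambda = 1` with a
#' cubic smoothing spline and clipped into (0, 1]. q-values follow by the
#' step-up rule `q(p_(i)) = min_\{j >= i\} pi0 m p_(j) / j`. Forcing
#' `pi0 = 1` reduces the procedure to Benjamini-Hochberg.
#'
#' @param p vector of p-values in \[0, 1\].
#' @param pi0 `"smoother"` (estimate) or `1` (force BH mode).
#' @param lambda evaluation grid for the pi0 estimate.
#' @return q-values in the original order, with attribute `pi0`.
#' @export
storey_q <- function(p, pi0 = c("smoother", "1"),
                     lambda = seq(0, 0.90, by = 0.05)) {
  if (length(p) == 0) validation_error("empty p-value vector")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    validation_error("p-values must lie in [0, 1]")
  }
  if (!is.character(pi0)) pi0 <- as.character(pi0)
  pi0 <- match.arg(pi0)
  m <- length(p)
  if (pi0 == "1" || m < 2) {
    pi0_hat <- 1
  } else {
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0_hat <- stats::predict(fit, x = max(lambda))$y
    pi0_hat <- min(max(pi0_hat, 1 / m), 1)
  }
  o <- order(p)
  q_ord <- pi0_hat * m * p[o] / seq_len(m)
  q_ord <- rev(cummin(rev(q_ord)))
  q_ord <- pmin(q_ord, 1)
  q <- numeric(m)
  q[o] <- q_ord
  attr(q, "pi0") <- pi0_hat
  q
}

#' Feature-by-clinical-measure Spearman correlation table
#'
#' One row per feature x clinical measure: complete-pair n, Spearman rho,
#' the t-approximation p, and a Storey q computed within the measure's
#' family (all features tested against one clinical measure form one
#' multiple-testing family, matching per-column starring of a correlation
#' table). Significance flags are reported at 0.05/0.01 on p and on q
#' separately.
#'
#' @param features tibble: `subject` plus one numeric column per feature.
#' @param clinical tibble: `subject` plus one numeric column per measure
#'   (e.g. the output of [msfc4_scores()] restricted to one visit).
#' @param measures which clinical columns to correlate against (default:
#'   every numeric column except `subject`/`visit`).
#' @param qvalue_pi0 passed to [storey_q()] (`"smoother"` or `1`).
#' @param min_n smallest complete-pair count kept (rows below are dropped
#'   with a warning).
#' @return an `ms_cortab` tibble: `feature`, `measure`, `n`, `rho`, `p`,
#'   `q`, `sig_p05`, `sig_p01`, `sig_q05`, `sig_q01`.
#' @export
correlation_table <- function(features, clinical, measures = NULL,
                              qvalue_pi0 = "smoother", min_n = 4) {
  if (!"subject" %in% names(features) || !"subject" %in% names(clinical)) {
    validation_error("both tables need a 'subject' column")
  }
  shared <- intersect(features$subject, clinical$subject)
  if (length(shared) == 0) validation_error("no shared subjects")
  f <- features[match(shared, features$subject), ]
  cl <- clinical[match(shared, clinical$subject), ]
  feat_cols <- setdiff(names(f)[vapply(f, is.numeric, logical(1))], "subject")
  if (is.null(measures)) {
    measures <- setdiff(names(cl)[vapply(cl, is.numeric, logical(1))],
                        c("subject", "visit"))
  }
  rows <- list()
  for (mcol in measures) {
    fam <- list()
    for (fc in feat_cols) {
      x <- f[[fc]]; y <- cl[[mcol]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < max(3, min_n)) {
        rlang::warn(sprintf("dropping %s x %s: only %d complete pairs",
                            fc, mcol, sum(ok)))
        next
      }
      rho <- spearman_rho(x, y)
      n <- attr(rho, "n")
      fam[[length(fam) + 1]] <- tibble::tibble(
        feature = fc, measure = mcol, n = n, rho = as.numeric(rho),
        p = spearman_pvalue(as.numeric(rho), n))
    }
    fam <- dplyr::bind_rows(fam)
    if (nrow(fam) == 0) next
    fam$q <- as.numeric(storey_q(fam$p, pi0 = qvalue_pi0))
    rows[[length(rows) + 1]] <- fam
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out,
                       sig_p05 = .data$p <= 0.05, sig_p01 = .data$p <= 0.01,
                       sig_q05 = .data$q <= 0.05, sig_q01 = .data$q <= 0.01)
  class(out) <- c("ms_cortab", class(tibble::tibble()))
  out
}

#' Variability of the k-day median versus days observed
#'
#' For each window length k, random contiguous k-day blocks are drawn and
#' each block's median compared with the subject's full-period median; the
#' root-mean-square deviation across blocks is the reported variability.
#' Averaging more days concentrates the median, so the curve falls with k.
#'
#' @param daily tibble: `subject`, `day`, `value` (one value per
#'   subject-day, e.g. the daily median stance time).
#' @param k_grid window lengths in days; entries exceeding a subject's
#'   observed days are skipped with a warning.
#' @param n_resamples contiguous blocks drawn per (subject, k).
#' @param seed RNG seed.
#' @return an `ms_varcurve` tibble: `subject`, `k`, `se_median` plus the
#'   cohort mean rows (`subject = ".cohort"`).
#' @export
variability_vs_days <- function(daily, k_grid = c(1, 2, 4, 7, 14, 28, 49),
                                n_resamples = 200, seed = 1) {
  set.seed(seed)
  out <- list()
  for (sid in unique(daily$subject)) {
    dsub <- daily[daily$subject == sid, ]
    dsub <- dsub[order(dsub$day), ]
    vals <- dsub$value[is.finite(dsub$value)]
    nd <- length(vals)
    full_med <- median(vals)
    for (k in k_grid) {
      if (k > nd) {
        rlang::warn(sprintf("subject %s: k = %d exceeds %d observed days",
                            sid, k, nd))
        next
      }
      starts <- sample.int(nd - k + 1, n_resamples, replace = TRUE)
      meds <- vapply(starts, function(s) median(vals[s:(s + k - 1)]),
                     numeric(1))
      out[[length(out) + 1]] <- tibble::tibble(
        subject = sid, k = k,
        se_median = sqrt(mean((meds - full_med)^2)))
    }
  }
  res <- dplyr::bind_rows(out)
  coh <- res |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(se_median = mean(.data$se_median), .groups = "drop") |>
    dplyr::mutate(subject = ".cohort") |>
    dplyr::select("subject", "k", "se_median")
  res <- dplyr::bind_rows(res, coh)
  class(res) <- c("ms_varcurve", class(tibble::tibble()))
  res
}
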