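test_that("MSFC-4 z-scores follow the composite convention", {
  ref <- list(means = c(t25fw_s = 6, nhpt_s = 22, sdmt_correct = 50,
                        lcva_correct = 55),
              sds = c(t25fw_s = 2, nhpt_s = 5, sdmt_correct = 10,
                      lcva_correct = 8))
  at_mean <- tibble::tibble(subject = "S01", visit = 1, edss = 3,
                            t25fw_s = 6, nhpt_s = 22, sdmt_correct = 50,
                            lcva_correct = 55)
  z0 <- msfc4_scores(at_mean, reference = ref)
  expect_equal(z0$msfc4_composite, 0)
  # one sd slower on the walk: z_25fw = -1, composite -0.25
  slow <- at_mean; slow$t25fw_s <- 8
  z1 <- msfc4_scores(slow, reference = ref)
  expect_equal(z1$z_25fw, -1)
  expect_equal(z1$msfc4_composite, -0.25)
  # cohort-internal reference: composites of a symmetric pair sum to 0
  pair <- tibble::tibble(subject = c("A", "B"), visit = 1, edss = 2,
                         t25fw_s = c(5, 7), nhpt_s = c(18, 24),
                         sdmt_correct = c(60, 40), lcva_correct = c(60, 50))
  zz <- msfc4_scores(pair)
  expect_equal(sum(zz$msfc4_composite), 0)
  # zero-variance reference names the offending subscore
  const <- pair; const$sdmt_correct <- 50
  expect_error(msfc4_scores(const), "sdmt",
               class = "mswear_validation_error")
  # inverse 9HPT mode flips orientation consistently (faster = better)
  zi <- msfc4_scores(pair, nhpt_mode = "inverse")
  expect_gt(zi$z_9hpt[1], zi$z_9hpt[2])
})

test_that("spearman_rho equals the midrank oracle, ties included", {
  expect_equal(as.numeric(spearman_rho(1:3, c(10, 20, 30))), 1)
  expect_equal(as.numeric(spearman_rho(1:3, c(30, 20, 10))), -1)
  x <- c(1, 2, 2, 3); y <- c(1, 3, 2, 4)
  expect_equal(as.numeric(spearman_rho(x, y)), spearman_oracle(x, y))
  set.seed(42)
  for (i in 1:200) {
    n <- sample(5:30, 1)
    x <- sample(1:8, n, replace = TRUE)   # heavy ties
    y <- rnorm(n)
    expect_equal(as.numeric(spearman_rho(x, y)), spearman_oracle(x, y),
                 tolerance = 1e-12)
  }
  expect_error(spearman_rho(1:2, 1:2), class = "mswear_validation_error")
  expect_warning(r <- spearman_rho(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r))
})

test_that("the t-approximation p-value behaves at its boundaries", {
  expect_equal(spearman_pvalue(0, 10), 1)
  expect_equal(spearman_pvalue(1, 10), 0)
  # monotone decreasing in |rho|
  p <- spearman_pvalue(seq(0, 0.9, 0.1), 23)
  expect_true(all(diff(p) < 0))
  expect_equal(spearman_pvalue(-0.5, 23), spearman_pvalue(0.5, 23))
  expect_error(spearman_pvalue(0.5, 3), class = "mswear_validation_error")
})

test_that("storey_q reduces to Benjamini-Hochberg when pi0 is forced to 1", {
  q <- storey_q(c(0.005, 0.01, 0.03, 0.03), pi0 = 1)
  expect_equal(as.numeric(q), c(0.02, 0.02, 0.03, 0.03))
  expect_equal(as.numeric(storey_q(0.04, pi0 = 1)), 0.04)
  set.seed(7)
  for (i in 1:100) {
    m <- sample(3:40, 1)
    p <- runif(m)^sample(1:3, 1)  # mix of null-ish and signal-ish
    expect_equal(as.numeric(storey_q(p, pi0 = 1)), bh_oracle(p),
                 tolerance = 1e-12)
  }
})

test_that("storey_q estimates pi0 sensibly and keeps q monotone in p", {
  set.seed(11)
  p <- c(runif(150), rbeta(50, 0.2, 5))  # 75% true nulls
  q <- storey_q(p)
  pi0 <- attr(q, "pi0")
  expect_gt(pi0, 0.3); expect_lte(pi0, 1)
  # q sorted by p is non-decreasing
  expect_true(all(diff(as.numeric(q)[order(p)]) > -1e-12))
  # estimated-pi0 q-values never exceed the BH ones
  expect_true(all(as.numeric(q) <= bh_oracle(p) + 1e-12))
  expect_error(storey_q(c(0.5, 1.2)), class = "mswear_validation_error")
})

test_that("correlation_table recovers exact monotone structure", {
  prof <- subject_profiles(12, effect_config(noise_scale = 0), seed = 5)
  clin <- simulate_clinical_scores(prof, effect_config(noise_scale = 0))
  scores <- msfc4_scores(clin)
  feats <- tibble::tibble(subject = prof$subject_id,
                          stance = prof$stance_time_s,
                          sway = prof$sway_A_ml_mm)
  ct <- correlation_table(feats, dplyr::select(
    scores, "subject", "msfc4_composite"), measures = "msfc4_composite")
  expect_equal(ct$rho[ct$feature == "stance"], -1)
  expect_equal(ct$rho[ct$feature == "sway"], -1)
  # permuting both tables identically leaves the result unchanged
  o <- sample(nrow(feats))
  ct2 <- correlation_table(feats[o, ],
                           dplyr::select(scores, "subject",
                                         "msfc4_composite")[o, ],
                           measures = "msfc4_composite")
  expect_equal(as.data.frame(ct2), as.data.frame(ct))
  # per-row n honours pairwise deletion
  feats$stance[1:4] <- NA
  ct3 <- correlation_table(feats, dplyr::select(scores, "subject",
                                                "msfc4_composite"),
                           measures = "msfc4_composite")
  expect_equal(ct3$n[ct3$feature == "stance"], 8)
  expect_error(correlation_table(
    tibble::tibble(subject = "X", f = 1),
    tibble::tibble(subject = "Y", m = 1)),
    class = "mswear_validation_error")
})

test_that("tidiers and plots expose the correlation table", {
  prof <- subject_profiles(10, seed = 6)
  clin <- simulate_clinical_scores(prof, seed = 6)
  scores <- msfc4_scores(clin)
  feats <- tibble::tibble(subject = prof$subject_id,
                          stance = prof$stance_time_s)
  ct <- correlation_table(feats, dplyr::select(scores, "subject",
                                               "msfc4_composite"),
                          measures = "msfc4_composite")
  td <- tidy(ct)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "ms_cortab"))
  gl <- glance(ct)
  expect_equal(gl$n_tests, nrow(ct))
  expect_s3_class(autoplot(ct), "ggplot")
})

test_that("k-day median variability falls as days accumulate", {
  # constant series: identically zero curve
  const <- tibble::tibble(subject = "A", day = 1:56, value = 0.7)
  vc <- variability_vs_days(const, k_grid = c(1, 7), seed = 1)
  expect_true(all(vc$se_median == 0))
  # iid normal daily values: k = 49 beats k = 1 in every seed
  for (s in 1:20) {
    set.seed(s)
    daily <- tibble::tibble(subject = "A", day = 1:56, value = rnorm(56))
    vc <- variability_vs_days(daily, k_grid = c(1, 49), seed = s)
    coh <- vc[vc$subject == ".cohort", ]
    expect_lt(coh$se_median[coh$k == 49], coh$se_median[coh$k == 1])
  }
  # determinism and k overflow warning
  daily <- tibble::tibble(subject = "A", day = 1:10, value = rnorm(10))
  v1 <- variability_vs_days(daily, k_grid = c(1, 4), seed = 3)
  v2 <- variability_vs_days(daily, k_grid = c(1, 4), seed = 3)
  expect_identical(v1, v2)
  expect_warning(variability_vs_days(daily, k_grid = c(1, 20), seed = 3),
                 "exceeds")
  expect_s3_class(autoplot(v1), "ggplot")
  expect_gt(glance(v1)$se_at_k_min, 0)
})
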