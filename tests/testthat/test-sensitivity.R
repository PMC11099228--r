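test_that("Cochran's Q is zero with equal ratios and explodes for an outlier", {
  g <- c(0.1, 0.2, 0.3, 0.25)
  q0 <- cochran_q(make_h(g, 0.4 * g))
  expect_equal(q0$q, 0, tolerance = 1e-12)
  expect_equal(q0$pvalue, 1)
  expect_identical(q0$df, 3L)

  # single ratio displaced by ~10 z-units among 20 -> chi-square far tail
  set.seed(31)
  g20 <- runif(20, 0.15, 0.3)
  G20 <- 0.3 * g20 + rnorm(20, 0, 0.02)
  G20[7] <- G20[7] + 10 * 0.02
  q1 <- cochran_q(make_h(g20, G20, seG = 0.02))
  expect_lt(q1$pvalue, 1e-6)
})

test_that("Q from leave-one-out residual identity matches the direct formula", {
  set.seed(32)
  g <- rnorm(10, 0.2, 0.05)
  G <- 0.3 * g + rnorm(10, 0, 0.04)
  h <- make_h(g, G, seG = 0.04)
  q_direct <- cochran_q(h)$q
  # oracle: Q = sum over j of w_j (ratio_j - ivw)^2 recomputed longhand
  w <- g^2 / 0.04^2
  r <- G / g
  b <- sum(w * r) / sum(w)
  expect_equal(q_direct, sum(w * (r - b)^2), tolerance = 1e-9)
})

test_that("Egger intercept test pins exact data and stays centered under no pleiotropy", {
  g <- c(0.1, 0.2, 0.3)
  h <- make_h(g, 0.1 + 0.5 * g)
  et <- egger_intercept_test(h)
  expect_equal(et$intercept, 0.1, tolerance = 1e-9)
  # the overdispersion factor is floored at 1, so even a zero-residual fit
  # keeps the fixed-weights SE; with many exact points the test does reject
  g2 <- seq(0.05, 0.5, length.out = 30)
  et2 <- egger_intercept_test(make_h(g2, 0.1 + 0.5 * g2, seG = 0.01))
  expect_lt(et2$pvalue, 1e-6)

  set.seed(33)
  ints <- replicate(300, {
    gt <- abs(rnorm(40, 0, 0.15))
    g <- gt + rnorm(40, 0, 0.02)
    G <- 0.3 * gt + rnorm(40, 0, 0.04)
    egger_intercept_test(make_h(g, G, seg = 0.02, seG = 0.04))$intercept
  })
  mc_se <- sd(ints) / sqrt(length(ints))
  expect_lt(abs(mean(ints)), 2 * mc_se + 1e-3)
})

test_that("Egger intercept test has power against a = 0.08 at 150 SNPs", {
  set.seed(34)
  rejections <- replicate(200, {
    gt <- abs(rnorm(150, 0, 0.15))
    g <- gt + rnorm(150, 0, 0.02)
    G <- 0.08 + 0.2 * gt + rnorm(150, 0, 0.05)
    egger_intercept_test(make_h(g, G, seg = 0.02, seG = 0.05))$pvalue < 0.05
  })
  expect_gt(mean(rejections), 0.8)
})

test_that("MR-PRESSO is calm on clean data and flags a displaced instrument", {
  set.seed(35)
  clean_ok <- replicate(50, {
    g <- runif(20, 0.15, 0.3)
    G <- 0.3 * g + rnorm(20, 0, 0.02)
    mr_presso(make_h(g, G, seG = 0.02), n_sim = 300, seed = 1)$global_p > 0.05
  })
  expect_gte(mean(clean_ok), 0.9)

  g <- runif(20, 0.15, 0.3)
  G <- 0.3 * g + rnorm(20, 0, 0.02)
  G[5] <- G[5] + 10 * 0.02
  pr <- mr_presso(make_h(g, G, seG = 0.02), n_sim = 500, seed = 2)
  expect_true(sprintf("rs%03d", 5) %in% pr$outliers)
  # outlier-corrected refit recovers the clean truth
  expect_lt(abs(pr$estimate_outlier_corrected$beta - 0.3), 0.02)
  expect_false(is.na(pr$distortion_p))
})

test_that("MR-PRESSO is bit-reproducible for a fixed seed", {
  set.seed(36)
  g <- runif(12, 0.15, 0.3)
  G <- 0.3 * g + rnorm(12, 0, 0.03)
  h <- make_h(g, G, seG = 0.03)
  a <- mr_presso(h, 300, 0.05, seed = 7)
  b <- mr_presso(h, 300, 0.05, seed = 7)
  expect_identical(a$global_p, b$global_p)
  expect_identical(a$outlier_pvalues, b$outlier_pvalues)
})

test_that("leave-one-out returns k stable refits and isolates an influential SNP", {
  g <- rep(c(0.1, 0.2, 0.3, 0.25, 0.18), 1)
  loo0 <- leave_one_out(make_h(g, 0.4 * g))
  expect_identical(nrow(loo0), 5L)
  expect_true(all(abs(loo0$beta - 0.4) < 1e-12))

  set.seed(37)
  g20 <- runif(20, 0.15, 0.3)
  G20 <- 0.3 * g20 + rnorm(20, 0, 0.01)
  G20[11] <- G20[11] + 0.15
  h <- make_h(g20, G20, seG = 0.01)
  full <- mr_ivw(h)$beta
  loo <- leave_one_out(h)
  shift <- abs(loo$beta - full)
  spread <- max(shift[-11])
  expect_gt(shift[11], 3 * spread)

  expect_identical(nrow(leave_one_out(make_h(g[1:3], 0.4 * g[1:3]))), 3L)
})

test_that("homogeneity and null calibration: Q and IVW reject near nominal rate", {
  set.seed(38)
  n_rep <- 400
  stats <- replicate(n_rep, {
    gt <- rnorm(30, 0, 0.15)
    gt <- gt[abs(gt) > 0.08]
    k <- length(gt)
    if (k < 5) return(c(NA, NA))
    g <- gt + rnorm(k, 0, 0.02)
    G <- rnorm(k, 0, 0.03)  # pure noise outcome
    h <- make_h(g, G, seg = 0.02, seG = 0.03)
    c(q = cochran_q(h)$pvalue < 0.05, ivw = mr_ivw(h)$pvalue < 0.05)
  })
  q_rate <- mean(stats[1, ], na.rm = TRUE)
  ivw_rate <- mean(stats[2, ], na.rm = TRUE)
  expect_gt(q_rate, 0.02)
  expect_lt(q_rate, 0.09)
  expect_gt(ivw_rate, 0.02)
  expect_lt(ivw_rate, 0.09)
})

test_that("the sensitivity report raises flags per the decision rule", {
  set.seed(39)
  g <- runif(20, 0.15, 0.3)
  G <- 0.3 * g + rnorm(20, 0, 0.02)
  rep_clean <- sensitivity_report(make_h(g, G, seG = 0.02),
                                  mr_config(presso_n_sim = 300))
  expect_false(rep_clean$pleiotropy_flag)
  expect_identical(rep_clean$q_df, 19L)

  G2 <- 0.1 + 0.3 * g + rnorm(20, 0, 0.005)  # strong directional pleiotropy
  rep_pleio <- sensitivity_report(make_h(g, G2, seG = 0.005),
                                  mr_config(presso_n_sim = 300))
  expect_true(rep_pleio$pleiotropy_flag)
})
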