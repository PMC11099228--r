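test_that("Wald ratio arithmetic, degenerate numerator, and sign cancellation", {
  expect_equal(wald_ratio(make_h(0.1, 0.05, seG = 0.02))$beta, 0.5)
  expect_equal(wald_ratio(make_h(0.1, 0.05, seG = 0.02))$se, 0.2)
  zero <- wald_ratio(make_h(0.1, 0, seG = 0.02))
  expect_equal(zero$beta, 0)
  expect_equal(zero$pvalue, 1)
  expect_equal(wald_ratio(make_h(-0.1, -0.05, seG = 0.02))$beta, 0.5)
  expect_error(wald_ratio(make_h(0, 0.05)), class = "axismr_estimation_error")
})

test_that("IVW recovers an exact shared ratio with the closed-form fixed SE", {
  h <- make_h(c(0.1, 0.2, 0.3), c(0.05, 0.10, 0.15), seG = 0.1)
  est <- mr_ivw(h, "fixed")
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 1 / sqrt(14))  # sum(g^2)/seG^2 = 0.14/0.01
  # equal ratios leave no overdispersion: random-effects SE identical
  expect_equal(mr_ivw(h, "multiplicative_random")$se, 1 / sqrt(14))
  expect_error(mr_ivw(make_h(0.1, 0.05)), class = "axismr_estimation_error")
})

test_that("estimate invariants hold: CI from the normal quantile, OR = exp(beta)", {
  h <- make_h(c(0.1, 0.2, 0.3), c(0.07, 0.11, 0.12), seG = 0.1)
  for (est in list(mr_ivw(h), mr_egger(h), mr_weighted_median(h, 200, 1),
                   mr_mode(h, TRUE, 1, 200, 1))) {
    expect_equal(est$ci_low, est$beta - 1.959964 * est$se, tolerance = 1e-9)
    expect_equal(est$ci_high, est$beta + 1.959964 * est$se, tolerance = 1e-9)
    expect_equal(est$odds_ratio, exp(est$beta), tolerance = 1e-12)
  }
})

test_that("IVW is unbiased under the structural model", {
  # Monte-Carlo recovery oracle: 50 SNPs, true effect 0.3, no pleiotropy
  set.seed(314)
  n_rep <- 300
  est <- replicate(n_rep, {
    g_true <- rnorm(50, 0, 0.15)
    g <- g_true + rnorm(50, 0, 0.02)
    G <- 0.3 * g_true + rnorm(50, 0, 0.05)
    mr_ivw(make_h(g, G, seg = 0.02, seG = 0.05))$beta
  })
  expect_lt(abs(mean(est) - 0.3), 0.02)
})

test_that("Egger reproduces exact linear data and recovers a directional intercept", {
  g <- c(0.1, 0.2, 0.3)
  h <- make_h(g, 0.1 + 0.5 * g, seG = 0.1)
  est <- mr_egger(h)
  expect_equal(est$beta, 0.5, tolerance = 1e-9)
  expect_equal(est$extra$egger_intercept, 0.1, tolerance = 1e-9)

  set.seed(99)
  intercepts <- replicate(200, {
    gt <- abs(rnorm(100, 0, 0.15))
    g <- gt + rnorm(100, 0, 0.005)  # strong instruments: NOME near-satisfied
    G <- 0.05 + 0.2 * gt + rnorm(100, 0, 0.05)
    mr_egger(make_h(g, G, seg = 0.005, seG = 0.05))$extra$egger_intercept
  })
  expect_lt(abs(mean(intercepts) - 0.05), 0.01)
})

test_that("weighted median matches the cumulative-weight interpolation oracle", {
  # degenerate distribution
  g <- c(0.1, 0.2, 0.4)
  expect_equal(mr_weighted_median(make_h(g, 0.4 * g), 100, 1)$beta, 0.4)

  # equal weights, evenly spaced ratios -> plain median
  g5 <- rep(1, 5)
  G5 <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  expect_equal(mr_weighted_median(make_h(g5, G5), 100, 1)$beta, 0.3)

  set.seed(5)
  for (i in 1:50) {
    k <- sample(3:12, 1)
    ratio <- rnorm(k)
    weight <- runif(k, 0.1, 2)
    h <- make_h(rep(1, k), ratio, seG = 1 / sqrt(weight))
    expect_equal(mr_weighted_median(h, 50, 1)$beta,
                 oracle_weighted_median(ratio, weight), tolerance = 1e-12)
  }
})

test_that("weighted median resists 30% invalid instruments where IVW does not", {
  set.seed(2024)
  res <- replicate(200, {
    k <- 30
    g_true <- runif(k, 0.1, 0.3)
    g <- g_true + rnorm(k, 0, 0.01)
    pleio <- c(rep(1, 9), rep(0, k - 9))  # 30% with inflated ratios
    G <- 0.3 * g_true + pleio * 0.15 + rnorm(k, 0, 0.01)
    h <- make_h(g, G, seg = 0.01, seG = 0.01)
    c(wm = mr_weighted_median(h, 50, 1)$beta, ivw = mr_ivw(h)$beta)
  })
  expect_lt(abs(median(res["wm", ]) - 0.3), 0.03)
  expect_gt(median(res["ivw", ]) - 0.3, 0.1)  # IVW biased upward
})

test_that("mode estimator finds the density argmax of the ratio cluster", {
  g <- rep(1, 4)
  expect_equal(mr_mode(make_h(g, rep(0.25, 4)), TRUE, 1, 100, 1)$beta, 0.25)

  G <- c(0.3, 0.3, 0.3, 0.9)
  est <- mr_mode(make_h(g, G), weighted = FALSE, 1, 100, 1)
  ratio <- G
  scales <- c(sd(ratio), mad(ratio))
  bw <- 0.9 * min(scales[scales > 0]) * 4^(-1 / 5)
  oracle <- oracle_mode_grid(ratio, rep(1, 4), bw)
  expect_lt(abs(est$beta - oracle), 0.01)
  expect_lt(abs(est$beta - 0.3), 0.05)
})

test_that("mode estimate moves continuously with the bandwidth factor", {
  set.seed(8)
  g <- rep(1, 20)
  G <- c(rnorm(12, 0.3, 0.02), rnorm(8, 0.8, 0.02))
  factors <- seq(0.5, 2, by = 0.1)
  betas <- vapply(factors,
                  function(f) mr_mode(make_h(g, G), FALSE, f, 50, 1)$beta,
                  numeric(1))
  # within the regime dominated by the same cluster, steps are small
  jumps <- abs(diff(betas))
  expect_lt(sort(jumps, decreasing = TRUE)[2], 0.1)
})

test_that("all estimators are equivariant under joint per-SNP sign flips", {
  set.seed(17)
  k <- 12
  g <- rnorm(k, 0.2, 0.05)
  G <- 0.4 * g + rnorm(k, 0, 0.02)
  flip <- sample(c(-1, 1), k, replace = TRUE)
  h1 <- make_h(g, G, seg = 0.01, seG = 0.03)
  h2 <- make_h(g * flip, G * flip, seg = 0.01, seG = 0.03)
  expect_equal(mr_ivw(h1)$beta, mr_ivw(h2)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(h1)$beta, mr_egger(h2)$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_median(h1, 50, 1)$beta,
               mr_weighted_median(h2, 50, 1)$beta, tolerance = 1e-12)
  expect_equal(mr_mode(h1, TRUE, 1, 50, 1)$beta,
               mr_mode(h2, TRUE, 1, 50, 1)$beta, tolerance = 1e-9)
})

test_that("every estimator returns c exactly when all Wald ratios equal c", {
  g <- c(0.12, 0.2, 0.31, 0.4)
  h <- make_h(g, 0.7 * g)
  expect_equal(mr_ivw(h)$beta, 0.7, tolerance = 1e-12)
  expect_equal(mr_egger(h)$beta, 0.7, tolerance = 1e-9)
  expect_equal(mr_weighted_median(h, 50, 1)$beta, 0.7, tolerance = 1e-12)
  expect_equal(mr_mode(h, TRUE, 1, 50, 1)$beta, 0.7, tolerance = 1e-12)
  expect_equal(mr_mode(h, FALSE, 1, 50, 1)$beta, 0.7, tolerance = 1e-12)
})

test_that("seeded bootstrap standard errors are bit-reproducible", {
  h <- make_h(c(0.1, 0.2, 0.3, 0.15), c(0.04, 0.09, 0.11, 0.07), seG = 0.05)
  expect_identical(mr_weighted_median(h, 200, 42)$se,
                   mr_weighted_median(h, 200, 42)$se)
  expect_identical(mr_mode(h, TRUE, 1, 200, 42)$se,
                   mr_mode(h, TRUE, 1, 200, 42)$se)
})
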