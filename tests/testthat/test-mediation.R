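test_that("sign consistency reproduces the full truth table", {
  for (sb in c(-1, 1)) for (s1 in c(-1, 1)) for (sa in c(-1, 1)) {
    expected <- sign(s1 * sa) == sign(sb)
    expect_identical(sign_consistent(sb * 0.2, s1 * 0.3, sa * 0.5), expected)
  }
  expect_error(sign_consistent(0, 0.3, 0.5), class = "axismr_screening_error")
})

test_that("mediated effect and proportion arithmetic", {
  m <- mediation_effect(0.4, 0.2, 0.1, 0.05, 0.05)
  expect_equal(m$mediated, 0.02)
  expect_equal(m$proportion, 0.05)
  # joint sign flip of the two legs leaves the product unchanged
  m2 <- mediation_effect(0.4, -0.2, -0.1, 0.05, 0.05)
  expect_equal(m2$mediated, m$mediated)
  expect_error(mediation_effect(0, 0.2, 0.1, 0.05, 0.05),
               class = "axismr_screening_error")
})

test_that("delta-method CI for the product agrees with parametric simulation", {
  set.seed(41)
  cases <- list(c(b1 = 0.5, b2 = 0.2, s1 = 0.05, s2 = 0.04),
                c(b1 = -0.3, b2 = 0.4, s1 = 0.03, s2 = 0.06),
                c(b1 = 0.8, b2 = -0.5, s1 = 0.06, s2 = 0.05))
  for (cs in cases) {
    m <- mediation_effect(0.3, cs["b1"], cs["b2"], cs["s1"], cs["s2"])
    draws <- rnorm(10000, cs["b1"], cs["s1"]) * rnorm(10000, cs["b2"], cs["s2"])
    sim_ci <- quantile(draws, c(0.025, 0.975))
    width <- diff(unname(sim_ci))
    expect_lt(abs(m$ci_mediated[1] - sim_ci[1]), 0.1 * width)
    expect_lt(abs(m$ci_mediated[2] - sim_ci[2]), 0.1 * width)
  }
})

test_that("BH q-values match the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(42)
  for (i in 1:50) {
    p <- runif(sample(2:20, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q <= 1))
    expect_false(is.unsorted(q[order(p)]))
  }
  expect_error(bh_fdr(c(0.5, 0)), class = "axismr_input_error")
})

test_that("the bundled candidate screen holds 20 rows and yields 7/6 retention", {
  fix <- example_candidate_screen()
  expect_identical(nrow(fix), 20L)
  res <- apply_retention_rule(fix, alpha = 0.05)
  expect_identical(res$n_pathways, 7L)
  expect_identical(res$n_mediators, 6L)
  # the CCR7 pathway is retained; the CD45-on-lymphocyte one is not
  expect_true(any(grepl("CCR7", res$retained$mediator)))
  expect_false(any(res$retained$mediator == "CD45 on lymphocyte"))
})

test_that("step-1 screen recovers a genuine mediator and excludes a pleiotropic one", {
  st <- generate_study(sim_config(seed = 51))
  cfg <- mr_config(seed = 51)
  s1 <- screen_exposure_to_mediator(st$exposure, list(m = st$mediator),
                                    config = cfg)
  expect_true(s1$retained[s1$id == "m"])
  # the outcome-association exclusion trims the strongest instruments, so
  # beta1 recovers with a modest downward attenuation, not CI coverage
  expect_lt(abs(s1$beta[s1$id == "m"] - 0.5), 0.1)
  expect_gt(s1$beta[s1$id == "m"], 0.3)

  # strong directional pleiotropy trips the Egger intercept rule; the
  # generated outcome plays the mediator role so the pleiotropy lands on
  # the screened leg
  stp <- generate_null_study(sim_config(seed = 52, pleiotropy = "directional",
                                        pleiotropy_mean = 0.08,
                                        pleiotropy_sd = 0.02))
  s1p <- screen_exposure_to_mediator(stp$exposure, list(m = stp$outcome),
                                     config = mr_config(seed = 52))
  expect_identical(s1p$reason[s1p$id == "m"], "pleiotropy")
})

test_that("step-2 screen keeps a true mediator-outcome effect and drops a null one", {
  st <- generate_study(sim_config(seed = 53))
  cfg <- mr_config(seed = 53)
  s2 <- screen_mediator_to_outcome(list(m = st$mediator), st$outcome,
                                   config = cfg)
  expect_true(s2$retained[s2$id == "m"])
  expect_identical(sign(s2$beta[s2$id == "m"]), 1)  # beta2 > 0 in truth

  null_st <- generate_null_study(sim_config(seed = 54))
  s2n <- screen_mediator_to_outcome(list(m = null_st$mediator),
                                    null_st$outcome, config = mr_config(seed = 54))
  expect_false(s2n$retained[s2n$id == "m"])
})

test_that("estimate_mediation satisfies the proportion identity and step flags", {
  st <- generate_study(sim_config(seed = 55))
  cfg <- mr_config(seed = 55)
  row <- estimate_mediation(st$exposure, st$mediator, st$outcome, config = cfg)
  expect_equal(row$proportion * row$beta_total, row$beta1 * row$beta2,
               tolerance = 1e-12)
  expect_equal(row$mediated_effect, row$beta1 * row$beta2, tolerance = 1e-12)
  if (row$retained) {
    expect_identical(row$passed_steps, "step1,step2,sign,step4")
    expect_true(sign_consistent(row$beta_total, row$beta1, row$alpha))
  }
})

test_that("the full screen retains a genuine mediator with usable power", {
  # gentler effects with a larger outcome GWAS: the exclusion filter stays
  # quiet and all four gates have high power
  retained <- vapply(1:40, function(s) {
    st <- generate_study(sim_config(seed = 500 + s, beta1 = 0.25,
                                    beta2 = 0.1, direct_effect = 0.1,
                                    n_gwas_outcome = 9479))
    cfg <- mr_config(seed = 500 + s)
    res <- run_mediation_screen(list(e = st$exposure), list(m = st$mediator),
                                list(o = st$outcome), config = cfg)
    nrow(res$results) == 1
  }, logical(1))
  expect_gt(mean(retained), 0.8)
})

test_that("an all-null screen almost never retains a pathway", {
  retained <- vapply(1:30, function(s) {
    st <- generate_null_study(sim_config(seed = 600 + s))
    cfg <- mr_config(seed = 600 + s)
    res <- run_mediation_screen(list(e = st$exposure), list(m = st$mediator),
                                list(o = st$outcome), config = cfg)
    nrow(res$results)
  }, numeric(1))
  # four serial gates at ~5% each: essentially zero expected
  expect_lte(sum(retained), 1)
})
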