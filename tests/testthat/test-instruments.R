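test_that("p-value thresholding keeps exactly the sub-threshold records", {
  ds <- make_ds(c("a", "b", "c"), beta = rep(0.1, 3), se = rep(0.01, 3),
                pvalue = c(1e-6, 2e-5, 1e-4))
  expect_identical(threshold_candidates(ds, 1e-5)$snp_id, "a")
  expect_identical(nrow(threshold_candidates(ds, 1)), 3L)
})

test_that("a null GWAS yields essentially no genome-wide hits", {
  # binomial oracle: expected count 1000 * 5e-8 = 5e-5
  set.seed(42)
  z <- rnorm(1000)
  ds <- make_ds(sprintf("rs%d", 1:1000), beta = z * 0.01, se = 0.01)
  expect_identical(nrow(threshold_candidates(ds, 5e-8)), 0L)
})

test_that("F-statistic is the squared Wald z and is sign-invariant", {
  expect_equal(compute_f_statistic(0.05, 0.01), 25)
  expect_equal(compute_f_statistic(0, 0.3), 0)
  expect_equal(compute_f_statistic(-0.03, 0.01), 9)
})

test_that("palindrome detection covers exactly the A/T and C/G pairs", {
  alleles <- c("A", "C", "G", "T")
  for (a1 in alleles) for (a2 in setdiff(alleles, a1)) {
    expected <- paste(sort(c(a1, a2)), collapse = "") %in% c("AT", "CG")
    expect_identical(is_palindromic(a1, a2), expected)
  }
})

test_that("weak and rare instruments are filtered with a strict F cutoff", {
  # F values 400, 16, 400: the boundary SNP sits exactly at the cutoff
  ds <- make_ds(c("rare", "boundaryF", "good"),
                beta = c(0.2, 0.04, 0.2),
                se = c(0.01, 0.01, 0.01),
                eaf = c(0.995, 0.3, 0.5))
  out <- filter_weak_and_rare(ds, f_min = 16, maf_min = 0.01)
  # MAF 0.005 removed; F exactly 16 removed (strictly greater than); F 400 kept
  expect_identical(out$snp_id, "good")
  expect_identical(nrow(filter_weak_and_rare(ds, f_min = 10, maf_min = 0.01)),
                   2L)
})

test_that("greedy clumping follows ascending p and respects the window", {
  ids <- c("A", "B", "C")
  ds <- make_ds(ids, beta = rep(0.1, 3), se = rep(0.01, 3),
                pvalue = c(1e-8, 1e-7, 1e-6), pos = c(1e6, 2e6, 3e6))
  ld <- matrix(c(1, 0.5, 5e-4,
                 0.5, 1, 5e-4,
                 5e-4, 5e-4, 1), 3, dimnames = list(ids, ids))
  out <- ld_clump(ds, ld, r2_threshold = 0.001, window_kb = 10000)
  expect_identical(out$snp_id, c("A", "C"))

  # identity LD: everything kept
  expect_identical(nrow(ld_clump(ds, NULL, 0.001, 10000)), 3L)

  # window exclusion: high r2 but 20,000 kb apart
  far <- make_ds(c("X", "Y"), beta = c(0.1, 0.1), se = 0.01,
                 pvalue = c(1e-8, 1e-7), pos = c(1e6, 1e6 + 2e10 / 1000))
  ld2 <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  expect_identical(nrow(ld_clump(far, ld2, 0.001, 10000)), 2L)
})

test_that("clump output is maximal: no removed SNP can rejoin the accepted set", {
  set.seed(7)
  for (rep in 1:20) {
    k <- 8
    ids <- sprintf("s%d", 1:k)
    m <- matrix(sample(c(0, 0.5), k * k, replace = TRUE), k)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 1
    dimnames(m) <- list(ids, ids)
    ds <- make_ds(ids, beta = rep(0.1, k), se = 0.01,
                  pvalue = runif(k), pos = rep(1e6, k))
    kept <- ld_clump(ds, m, 0.4, 10000)$snp_id
    removed <- setdiff(ids, kept)
    for (r in removed) {
      expect_true(any(m[r, kept] >= 0.4),
                  label = sprintf("removed SNP %s re-addable (rep %d)", r, rep))
    }
  }
})

test_that("outcome-associated and unmatched instruments are removed with counts", {
  inst <- make_ds(sprintf("rs%d", 1:10), beta = rep(0.1, 10), se = 0.01)
  outcome <- make_ds(sprintf("rs%d", 1:8), beta = rep(0.01, 8), se = 0.01,
                     pvalue = c(1e-6, 1e-6, 1e-6, rep(1e-4, 5)))
  out <- exclude_outcome_associated(inst, outcome, 5e-5)
  # oracle: 10 - 3 excluded (p < 5e-5) - 2 unmatched (rs9, rs10) = 5
  expect_identical(nrow(out), 5L)
  expect_identical(attr(out, "n_excluded"), 3L)
  expect_identical(attr(out, "n_unmatched"), 2L)
  expect_true(all(out$snp_id %in% sprintf("rs%d", 4:8)))
})

test_that("harmonization resolves swapped, complemented, and palindromic alleles", {
  exposure <- make_ds(c("swap", "comp", "pal"),
                      beta = c(0.1, 0.2, 0.3), se = 0.01,
                      effect_allele = c("A", "A", "A"),
                      other_allele = c("G", "G", "T"))
  outcome <- make_ds(c("swap", "comp", "pal"),
                     beta = c(-0.05, 0.07, 0.2), se = 0.02,
                     effect_allele = c("G", "T", "A"),
                     other_allele = c("A", "C", "T"))
  h <- harmonize(exposure, outcome, drop_palindromic = TRUE)
  expect_identical(h$snp_id, c("swap", "comp"))
  expect_equal(h$outcome_beta[h$snp_id == "swap"], 0.05)   # swap negates
  expect_equal(h$outcome_beta[h$snp_id == "comp"], 0.07)   # strand flip only
  expect_identical(attr(h, "n_palindromic_dropped"), 1L)
})

test_that("harmonization is idempotent on already-aligned pairs", {
  exposure <- make_ds(c("a", "b"), beta = c(0.1, -0.2), se = 0.01)
  outcome <- make_ds(c("a", "b"), beta = c(0.05, 0.03), se = 0.02)
  h <- harmonize(exposure, outcome)
  expect_equal(h$outcome_beta, outcome$beta)
  expect_equal(h$exposure_beta, exposure$beta)
})

test_that("zero overlap is an estimation error", {
  a <- make_ds("a", 0.1, 0.01)
  b <- make_ds("b", 0.1, 0.01)
  expect_error(harmonize(a, b), class = "axismr_estimation_error")
})

test_that("the composed selection cascade is deterministic", {
  st <- generate_study(sim_config(seed = 11))
  h1 <- select_instruments(st$exposure, st$outcome, config = mr_config())
  h2 <- select_instruments(st$exposure, st$outcome, config = mr_config())
  expect_identical(as.data.frame(h1), as.data.frame(h2))
  expect_false(is.unsorted(h1$exposure_pvalue))  # acceptance order: ascending p
})
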