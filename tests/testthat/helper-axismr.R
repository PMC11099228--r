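# Shared fixtures and independent oracles. Oracles re-derive each quantity
# from its definition, deliberately avoiding the package's code paths.

# Quick summary_dataset builder with sensible defaults.
make_ds <- function(snp_id, beta, se, pvalue = NULL,
                    effect_allele = NULL, other_allele = NULL,
                    eaf = 0.3, chrom = "1", pos = NULL, n = 1000,
                    trait = "trait", scale = "continuous") {
  k <- length(snp_id)
  if (is.null(pvalue)) pvalue <- 2 * pnorm(-abs(beta / se))
  if (is.null(effect_allele)) effect_allele <- rep("A", k)
  if (is.null(other_allele)) other_allele <- rep("G", k)
  if (is.null(pos)) pos <- seq_len(k) * 1000
  # fixture p-values are often deliberately unrelated to beta/se; silence
  # the soft consistency warning
  suppressWarnings(summary_dataset(data.frame(
    snp_id = snp_id, chrom = rep_len(chrom, k), pos = pos,
    effect_allele = rep_len(effect_allele, k),
    other_allele = rep_len(other_allele, k),
    eaf = rep_len(eaf, k), beta = beta, se = se, pvalue = pvalue,
    n = rep_len(n, k), stringsAsFactors = FALSE),
    trait_id = trait, trait_scale = scale, quiet = TRUE))
}

# Quick harmonized_set builder.
make_h <- function(g, G, seg = 0.01, seG = 0.1, ids = NULL) {
  k <- length(g)
  harmonized_set(snp_id = ids %||% sprintf("rs%03d", seq_len(k)),
                 exposure_beta = g, exposure_se = rep_len(seg, k),
                 outcome_beta = G, outcome_se = rep_len(seG, k))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Oracle: weighted median by explicit cumulative-weight interpolation.
oracle_weighted_median <- function(ratio, weight) {
  o <- order(ratio)
  r <- ratio[o]
  w <- weight[o] / sum(weight)
  s <- numeric(length(w))
  acc <- 0
  for (i in seq_along(w)) {
    s[i] <- acc + w[i] / 2
    acc <- acc + w[i]
  }
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  i <- max(which(s <= 0.5))
  r[i] + (r[i + 1] - r[i]) * (0.5 - s[i]) / (s[i + 1] - s[i])
}

# Oracle: Benjamini-Hochberg step-up from its definition
# q_(i) = min_{j >= i} p_(j) * m / j, mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Oracle: exhaustive greedy clump — literal restatement of the acceptance
# rule, scanning candidates in ascending-p order and testing every accepted
# SNP (no early exit, no window logic shortcuts).
oracle_clump <- function(snp_ids, pvalues, chrom, pos, ld, r2_threshold,
                         window_kb) {
  ord <- order(pvalues)
  accepted <- character(0)
  for (i in ord) {
    conflict <- FALSE
    for (a in accepted) {
      ia <- match(a, snp_ids)
      same_chrom <- chrom[i] == chrom[ia]
      close <- abs(pos[i] - pos[ia]) <= window_kb * 1000
      r2 <- if (snp_ids[i] %in% rownames(ld) && a %in% rownames(ld)) {
        ld[snp_ids[i], a]
      } else 0
      if (same_chrom && close && r2 >= r2_threshold) conflict <- TRUE
    }
    if (!conflict) accepted <- c(accepted, snp_ids[i])
  }
  accepted
}

# Oracle: brute-force weighted Gaussian-kernel density argmax on a dense
# grid.
oracle_mode_grid <- function(ratio, weight, bw, n_grid = 10001) {
  grid <- seq(min(ratio) - 3 * bw, max(ratio) + 3 * bw, length.out = n_grid)
  w <- weight / sum(weight)
  dens <- vapply(grid, function(x) sum(w * dnorm((x - ratio) / bw)) / bw,
                 numeric(1))
  grid[which.max(dens)]
}

# Build a synthetic trait pair with genuine effects in both directions:
# b12 (T1 -> T2) through T1's instruments, b21 (T2 -> T1) through T2's.
# Per-SNP cross-trait associations are kept modest (z ~ 2) so they clear
# the outcome-association exclusion while the combined MR signal is strong.
make_bidirectional_pair <- function(b12, b21, k = 40, seed = 99) {
  withr_seed <- function(s, expr) axismr:::with_seed(s, expr)
  withr_seed(seed, {
    se1 <- 0.02
    se2 <- 0.02
    g1 <- runif(k, 0.25, 0.4) * sample(c(-1, 1), k, replace = TRUE)
    g2 <- runif(k, 0.25, 0.4) * sample(c(-1, 1), k, replace = TRUE)
    snp1 <- sprintf("rsA%03d", seq_len(k))
    snp2 <- sprintf("rsB%03d", seq_len(k))
    t1_beta <- c(g1 + rnorm(k, 0, se1), b21 * g2 + rnorm(k, 0, se1))
    t2_beta <- c(b12 * g1 + rnorm(k, 0, se2), g2 + rnorm(k, 0, se2))
    pos <- seq_along(c(snp1, snp2)) * 2e7
    t1 <- make_ds(c(snp1, snp2), t1_beta, se1, pos = pos, trait = "t1")
    t2 <- make_ds(c(snp1, snp2), t2_beta, se2, pos = pos, trait = "t2")
    list(t1 = t1, t2 = t2)
  })
}
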