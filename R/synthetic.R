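# Seeded generator of two-sample GWAS summary statistics with known causal
# structure exposure -> mediator -> outcome, used to validate every pipeline
# stage without external downloads.
#
# Structural model on per-SNP true effects:
#   exposure instruments  j:  gamma_j ~ N(0, effect_sd^2)
#   mediator instruments  j:  delta_j ~ N(0, effect_sd^2)
#   true mediator effect:     beta1 * gamma_j   (exposure SNPs) | delta_j
#   true outcome effect:      (direct_effect + beta1*beta2) * gamma_j
#                             + pleiotropy_j    (exposure SNPs)
#                             | beta2 * delta_j (mediator SNPs)
# Observed betas add N(0, se^2) noise with se = 1/sqrt(2 n eaf (1-eaf)).
# Binary outcomes are simulated directly on the log-odds scale; `n` for the
# outcome is an effective sample size. LD is not simulated: instruments are
# independent, emulating post-clumping data. A block-diagonal LD injector
# exists solely to exercise the clumping code.

#' Simulation configuration
#'
#' Defaults emulate the motivating study design: a shotgun-metagenomics gut
#' microbiota GWAS of 7,738 samples (exposure), a 3,757-sample immune-cell
#' phenotype GWAS (mediator), and a small-cell lung-cancer case-control GWAS
#' (717 cases / 313,476 controls) collapsed to its effective sample size
#' `4/(1/cases + 1/controls) = 2,861` on the log-odds scale (outcome).
#' The outcome precision matters beyond statistical power: instruments for
#' an exposure with a real effect on the outcome are themselves associated
#' with the outcome, and when the outcome GWAS is precise enough to detect
#' those induced associations at the 5e-5 exclusion threshold, the
#' outcome-association filter removes the strongest instruments and biases
#' IVW toward zero. The default emulates a subtype-sized case-control
#' outcome where the filter behaves as intended.
#' `effect_sd = 0.15` yields instruments whose F-statistics after the p <
#' 1e-5 selection sit comfortably above 15.
#'
#' @param n_snp_exposure,n_snp_mediator number of instrument SNPs with true
#'   effects on the exposure / mediator.
#' @param n_gwas_exposure,n_gwas_mediator,n_gwas_outcome GWAS sample sizes
#'   (the outcome's is an effective size on the log-odds scale).
#' @param beta1 exposure -> mediator causal effect.
#' @param beta2 mediator -> outcome direct causal effect.
#' @param direct_effect exposure -> outcome effect not through the mediator.
#' @param pleiotropy `"none"`, `"balanced"` (mean-zero, InSIDE-satisfying),
#'   or `"directional"` (constant mean `pleiotropy_mean`); drawn
#'   independently of the instrument effects.
#' @param pleiotropy_mean mean of directional pleiotropy terms.
#' @param pleiotropy_sd SD of the pleiotropy terms.
#' @param eaf_range effect-allele frequency range, a sub-interval of
#'   (0, 0.5].
#' @param effect_sd SD of the per-SNP true instrument effects.
#' @param palindromic_rate fraction of SNPs given A/T or C/G alleles (decoys
#'   removed during harmonization).
#' @param low_maf_rate fraction of SNPs given MAF below 0.01 (decoys removed
#'   by the MAF filter).
#' @param seed integer seed; generation is fully reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snp_exposure = 100,
                       n_snp_mediator = 100,
                       n_gwas_exposure = 7738,
                       n_gwas_mediator = 3757,
                       n_gwas_outcome = 2861,
                       beta1 = 0.5,
                       beta2 = 0.2,
                       direct_effect = 0.2,
                       pleiotropy = c("none", "balanced", "directional"),
                       pleiotropy_mean = 0.05,
                       pleiotropy_sd = 0.05,
                       eaf_range = c(0.05, 0.5),
                       effect_sd = 0.15,
                       palindromic_rate = 0.05,
                       low_maf_rate = 0.02,
                       seed = 1L) {
  pleiotropy <- match.arg(pleiotropy)
  if (length(eaf_range) != 2 || eaf_range[1] >= eaf_range[2] ||
      eaf_range[1] <= 0 || eaf_range[2] > 0.5) {
    config_error("eaf_range must be an increasing interval within (0, 0.5]")
  }
  if (effect_sd <= 0) config_error("effect_sd must be positive")
  structure(list(n_snp_exposure = n_snp_exposure,
                 n_snp_mediator = n_snp_mediator,
                 n_gwas_exposure = n_gwas_exposure,
                 n_gwas_mediator = n_gwas_mediator,
                 n_gwas_outcome = n_gwas_outcome,
                 beta1 = beta1, beta2 = beta2, direct_effect = direct_effect,
                 pleiotropy = pleiotropy,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 eaf_range = eaf_range, effect_sd = effect_sd,
                 palindromic_rate = palindromic_rate,
                 low_maf_rate = low_maf_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

NONPALINDROMIC_PAIRS <- list(c("A", "C"), c("A", "G"), c("C", "A"),
                             c("C", "T"), c("G", "A"), c("G", "T"),
                             c("T", "C"), c("T", "G"))
PALINDROMIC_PAIRS <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

se_from_n_eaf <- function(n, eaf) 1 / sqrt(2 * n * eaf * (1 - eaf))

observe <- function(true_beta, se) {
  beta <- stats::rnorm(length(true_beta), true_beta, se)
  list(beta = beta, pvalue = z_to_p(beta / se))
}

#' Generate a three-trait study with known causal truth
#'
#' Draws per-SNP instrument effects, propagates them through the structural
#' model (see the package vignette), adds sampling noise appropriate to each
#' GWAS sample size, and returns the three summary datasets plus the ground
#' truth. Decoy palindromic and low-MAF SNPs are injected at the configured
#' rates. Fully deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return List with elements `exposure`, `mediator`, `outcome` (each a
#'   [summary_dataset()]), and `truth` (class `sim_truth`): the structural
#'   parameters, the implied `total_effect = direct_effect + beta1*beta2`,
#'   `alpha_marginal` (the population IVW slope a univariable mediator ->
#'   outcome analysis targets, including the exposure-confounded
#'   contribution), `proportion_true = beta1*beta2/total_effect`, and the
#'   per-SNP true effects.
#' @export
generate_study <- function(cfg = sim_config()) {
  with_seed(cfg$seed, {
    kx <- cfg$n_snp_exposure
    km <- cfg$n_snp_mediator
    k <- kx + km
    snp_id <- sprintf("rs%06d", seq_len(k))
    origin <- rep(c("exposure", "mediator"), c(kx, km))
    chrom <- as.character(rep_len(1:22, k))
    pos <- 1e6 + 2e7 * (seq_len(k) %/% 22)  # far apart: no positional LD

    eaf <- stats::runif(k, cfg$eaf_range[1], cfg$eaf_range[2])
    low_maf <- stats::runif(k) < cfg$low_maf_rate
    eaf[low_maf] <- stats::runif(sum(low_maf), 0.001, 0.009)
    pal <- stats::runif(k) < cfg$palindromic_rate
    pair_idx_np <- sample.int(length(NONPALINDROMIC_PAIRS), k, replace = TRUE)
    pair_idx_p <- sample.int(length(PALINDROMIC_PAIRS), k, replace = TRUE)
    a1 <- ifelse(pal,
                 vapply(pair_idx_p, function(i) PALINDROMIC_PAIRS[[i]][1], ""),
                 vapply(pair_idx_np, function(i) NONPALINDROMIC_PAIRS[[i]][1], ""))
    a2 <- ifelse(pal,
                 vapply(pair_idx_p, function(i) PALINDROMIC_PAIRS[[i]][2], ""),
                 vapply(pair_idx_np, function(i) NONPALINDROMIC_PAIRS[[i]][2], ""))

    gamma <- ifelse(origin == "exposure",
                    stats::rnorm(k, 0, cfg$effect_sd), 0)
    delta <- ifelse(origin == "mediator",
                    stats::rnorm(k, 0, cfg$effect_sd), 0)
    # Directional pleiotropy acts on the exposure-increasing allele, so its
    # mean is applied along sign(gamma); balanced pleiotropy is mean-zero
    # and independent of gamma (InSIDE holds in both modes).
    pleio <- switch(cfg$pleiotropy,
                    none = numeric(k),
                    balanced = ifelse(origin == "exposure",
                                      stats::rnorm(k, 0, cfg$pleiotropy_sd), 0),
                    directional = ifelse(origin == "exposure",
                                         sign(gamma) *
                                           stats::rnorm(k, cfg$pleiotropy_mean,
                                                        cfg$pleiotropy_sd), 0))

    true_x <- gamma
    true_m <- cfg$beta1 * gamma + delta
    total <- cfg$direct_effect + cfg$beta1 * cfg$beta2
    true_y <- cfg$direct_effect * gamma + cfg$beta2 * true_m + pleio

    se_x <- se_from_n_eaf(cfg$n_gwas_exposure, eaf)
    se_m <- se_from_n_eaf(cfg$n_gwas_mediator, eaf)
    se_y <- se_from_n_eaf(cfg$n_gwas_outcome, eaf)
    ox <- observe(true_x, se_x)
    om <- observe(true_m, se_m)
    oy <- observe(true_y, se_y)

    mk <- function(obs, se, n, id, scale) {
      summary_dataset(data.frame(
        snp_id = snp_id, chrom = chrom, pos = pos,
        effect_allele = a1, other_allele = a2, eaf = eaf,
        beta = obs$beta, se = se, pvalue = obs$pvalue, n = n,
        stringsAsFactors = FALSE), trait_id = id, trait_scale = scale,
        quiet = TRUE)
    }
    exposure <- mk(ox, se_x, cfg$n_gwas_exposure, "sim_exposure", "continuous")
    mediator <- mk(om, se_m, cfg$n_gwas_mediator, "sim_mediator", "continuous")
    outcome <- mk(oy, se_y, cfg$n_gwas_outcome, "sim_outcome", "log_odds")

    # Population IVW slope a univariable mediator -> outcome analysis
    # targets over all instruments (exposure SNPs contribute the confounded
    # direct-path term).
    w <- 1 / se_y^2
    denom <- sum(w * true_m^2)
    alpha_marginal <- if (denom > 0) sum(w * true_m * true_y) / denom else NA_real_

    truth <- structure(list(
      total_effect = total,
      beta1 = cfg$beta1, beta2 = cfg$beta2,
      direct_effect = cfg$direct_effect,
      alpha_marginal = alpha_marginal,
      proportion_true = if (total != 0) cfg$beta1 * cfg$beta2 / total else NA_real_,
      proportion_undefined = total == 0,
      per_snp = data.frame(snp_id = snp_id, origin = origin,
                           true_exposure = true_x, true_mediator = true_m,
                           true_outcome = true_y, pleiotropy = pleio,
                           stringsAsFactors = FALSE),
      config = cfg), class = "sim_truth")

    list(exposure = exposure, mediator = mediator, outcome = outcome,
         truth = truth)
  })
}

#' Generate a study with all causal parameters zero
#'
#' As [generate_study()] with `beta1 = beta2 = direct_effect = 0`:
#' instruments keep their strength, but no trait causally affects another.
#' The true mediation proportion is undefined.
#'
#' @param cfg a [sim_config()]; its causal parameters are overridden.
#' @return As [generate_study()].
#' @export
generate_null_study <- function(cfg = sim_config()) {
  cfg$beta1 <- 0
  cfg$beta2 <- 0
  cfg$direct_effect <- 0
  generate_study(cfg)
}

#' Block-diagonal LD matrix injector
#'
#' Builds an r-squared matrix where consecutive blocks of `block_size` SNPs
#' share `r2_within` and SNPs in different blocks are independent. Intended
#' solely to exercise [ld_clump()]; the study generator itself does not
#' simulate LD.
#'
#' @param snp_ids character vector of SNP ids.
#' @param block_size SNPs per block.
#' @param r2_within within-block r-squared in \[0, 1).
#' @return Symmetric matrix with unit diagonal and `snp_ids` dimnames.
#' @export
simulate_ld_blocks <- function(snp_ids, block_size = 2, r2_within = 0.5) {
  k <- length(snp_ids)
  block <- (seq_len(k) - 1) %/% block_size
  m <- outer(block, block, function(a, b) ifelse(a == b, r2_within, 0))
  diag(m) <- 1
  dimnames(m) <- list(snp_ids, snp_ids)
  m
}

#' Write a generated study to disk
#'
#' Writes the three summary datasets as tab-separated files and the ground
#' truth (with the echoed configuration and seed) as a JSON sidecar.
#'
#' @param study result of [generate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_summary_stats(study$exposure, file.path(dir, "exposure.tsv"))
  write_summary_stats(study$mediator, file.path(dir, "mediator.tsv"))
  write_summary_stats(study$outcome, file.path(dir, "outcome.tsv"))
  truth <- study$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
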