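# Instrumental-variable selection and exposure/outcome harmonization.
#
# The selection cascade mirrors common summary-data MR practice: genome-wide
# thresholding, greedy LD clumping, exclusion of outcome-associated SNPs,
# palindromic-SNP removal during harmonization, and weak-instrument /
# rare-variant filters.

#' Default analysis configuration
#'
#' Returns the configuration list consumed by the selection, estimation, and
#' screening functions. All values are overridable by name.
#'
#' @param iv_p_threshold genome-wide significance threshold for instruments
#'   of exposures and mediators (default `1e-5`).
#' @param reverse_iv_p_threshold instrument threshold when a disease outcome
#'   is used as the exposure in reverse MR (default `5e-8`).
#' @param clump_r2 LD r-squared ceiling for clumping (default `0.001`).
#' @param clump_window_kb clumping window in kilobases (default `10000`).
#' @param outcome_assoc_p instruments with an outcome-side p-value below this
#'   are excluded as directly outcome-associated (default `5e-5`).
#' @param f_min instruments must have F-statistic strictly greater than this
#'   (default `10`).
#' @param maf_min minimum minor allele frequency (default `0.01`).
#' @param drop_palindromic drop A/T and C/G SNPs during harmonization
#'   (default `TRUE`).
#' @param alpha significance level used by screens and flags (default `0.05`).
#' @param n_boot bootstrap resamples for median/mode standard errors.
#' @param presso_n_sim MR-PRESSO simulation count.
#' @param presso_outlier_p MR-PRESSO outlier significance level (Bonferroni
#'   adjusted across SNPs).
#' @param use_presso run MR-PRESSO inside screening steps (the Egger
#'   intercept test always runs); disable for large simulation studies.
#' @param seed integer seed for all stochastic components.
#' @return Named list of settings.
#' @export
mr_config <- function(iv_p_threshold = 1e-5,
                      reverse_iv_p_threshold = 5e-8,
                      clump_r2 = 0.001,
                      clump_window_kb = 10000,
                      outcome_assoc_p = 5e-5,
                      f_min = 10,
                      maf_min = 0.01,
                      drop_palindromic = TRUE,
                      alpha = 0.05,
                      n_boot = 1000,
                      presso_n_sim = 1000,
                      presso_outlier_p = 0.05,
                      use_presso = FALSE,
                      seed = 1L) {
  list(iv_p_threshold = iv_p_threshold,
       reverse_iv_p_threshold = reverse_iv_p_threshold,
       clump_r2 = clump_r2,
       clump_window_kb = clump_window_kb,
       outcome_assoc_p = outcome_assoc_p,
       f_min = f_min,
       maf_min = maf_min,
       drop_palindromic = drop_palindromic,
       alpha = alpha,
       n_boot = n_boot,
       presso_n_sim = presso_n_sim,
       presso_outlier_p = presso_outlier_p,
       use_presso = use_presso,
       seed = as.integer(seed))
}

#' Retain genome-wide significant candidate instruments
#'
#' Keeps exactly the records with `pvalue < p_threshold` (strict).
#'
#' @param ds a [summary_dataset()].
#' @param p_threshold significance threshold in (0, 1].
#' @return Filtered [summary_dataset()].
#' @export
threshold_candidates <- function(ds, p_threshold) {
  if (!(p_threshold > 0 && p_threshold <= 1)) {
    config_error("p_threshold must lie in (0, 1]")
  }
  reindex_dataset(ds, ds$pvalue < p_threshold)
}

#' Per-SNP instrument strength F-statistic
#'
#' The summary-data approximation `F = (beta/se)^2`, the square of the Wald
#' z-statistic. Vectorized over rows of a dataset or over beta/se vectors.
#'
#' @param beta effect estimate(s) or a [summary_dataset()].
#' @param se standard error(s); ignored when `beta` is a dataset.
#' @return Numeric vector of F-statistics.
#' @export
compute_f_statistic <- function(beta, se = NULL) {
  if (is.data.frame(beta)) {
    se <- beta$se
    beta <- beta$beta
  }
  if (any(se <= 0)) input_error("se must be positive")
  (beta / se)^2
}

#' Is an allele pair palindromic?
#'
#' TRUE iff the unordered pair is {A,T} or {C,G}; such SNPs cannot be strand
#' resolved from alleles alone. Vectorized.
#'
#' @param a1,a2 allele character vectors.
#' @return Logical vector.
#' @export
is_palindromic <- function(a1, a2) {
  a1 <- toupper(a1)
  a2 <- toupper(a2)
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Greedy LD clumping against an r-squared matrix
#'
#' Sorts candidates by ascending p-value (stable in input order for ties) and
#' accepts a SNP iff its r-squared with every already-accepted SNP on the
#' same chromosome within `window_kb` is strictly below `r2_threshold`. SNP
#' pairs absent from `ld` are treated as independent. The output preserves
#' acceptance order (ascending p).
#'
#' @param ds a [summary_dataset()].
#' @param ld optional LD matrix from [read_ld_matrix()] /
#'   [validate_ld_matrix()]; `NULL` treats all SNPs as independent.
#' @param r2_threshold r-squared ceiling in (0, 1).
#' @param window_kb window in kilobases within which LD is considered.
#' @return Clumped [summary_dataset()] in acceptance order.
#' @export
ld_clump <- function(ds, ld = NULL, r2_threshold = 0.001, window_kb = 10000) {
  if (!(r2_threshold > 0 && r2_threshold < 1)) {
    config_error("r2_threshold must lie in (0, 1)")
  }
  if (nrow(ds) == 0) return(ds)
  ord <- order(ds$pvalue)  # stable for ties
  accepted <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in accepted) {
      same_chrom <- ds$chrom[i] == ds$chrom[j]
      within <- abs(ds$pos[i] - ds$pos[j]) <= window_kb * 1000
      if (same_chrom && within &&
          ld_r2(ld, ds$snp_id[i], ds$snp_id[j]) >= r2_threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) accepted <- c(accepted, i)
  }
  reindex_dataset(ds, accepted)
}

#' Exclude instruments directly associated with the outcome
#'
#' Removes instruments whose outcome-side p-value is below `p_cut`;
#' instruments absent from the outcome dataset are removed as unmatched.
#' Exclusion and unmatched counts are attached as attributes
#' `n_excluded` / `n_unmatched`.
#'
#' @param instruments exposure-side [summary_dataset()] of instruments.
#' @param outcome outcome [summary_dataset()]; matching is by `snp_id`.
#' @param p_cut outcome-association exclusion threshold (default `5e-5`).
#' @return Filtered [summary_dataset()] with count attributes.
#' @export
exclude_outcome_associated <- function(instruments, outcome, p_cut = 5e-5) {
  idx <- match(instruments$snp_id, outcome$snp_id)
  unmatched <- is.na(idx)
  outcome_p <- rep(NA_real_, nrow(instruments))
  outcome_p[!unmatched] <- outcome$pvalue[idx[!unmatched]]
  excluded <- !unmatched & outcome_p < p_cut
  keep <- !unmatched & !excluded
  out <- reindex_dataset(instruments, keep)
  attr(out, "n_excluded") <- sum(excluded)
  attr(out, "n_unmatched") <- sum(unmatched)
  out
}

#' Filter weak and rare instruments
#'
#' Retains records with F-statistic strictly greater than `f_min` and minor
#' allele frequency `min(eaf, 1 - eaf)` at least `maf_min`.
#'
#' @param instruments a [summary_dataset()].
#' @param f_min weak-instrument threshold (strict; default `10`).
#' @param maf_min minimum MAF in \[0, 0.5\] (default `0.01`).
#' @return Filtered [summary_dataset()].
#' @export
filter_weak_and_rare <- function(instruments, f_min = 10, maf_min = 0.01) {
  if (f_min < 0) config_error("f_min must be non-negative")
  if (maf_min < 0 || maf_min > 0.5) config_error("maf_min must lie in [0, 0.5]")
  f <- compute_f_statistic(instruments)
  maf <- pmin(instruments$eaf, 1 - instruments$eaf)
  reindex_dataset(instruments, f > f_min & maf >= maf_min)
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Construct a harmonized exposure/outcome set directly
#'
#' Low-level constructor used by [harmonize()], the simulator, and tests.
#' All effects must already refer to the same effect allele per SNP.
#'
#' @param snp_id character vector of unique SNP ids.
#' @param exposure_beta,exposure_se exposure-side effects and SEs.
#' @param outcome_beta,outcome_se outcome-side effects and SEs.
#' @param exposure_id,outcome_id trait identifiers.
#' @param extra optional data frame of additional aligned columns.
#' @return A `harmonized_set` data frame.
#' @export
harmonized_set <- function(snp_id, exposure_beta, exposure_se,
                           outcome_beta, outcome_se,
                           exposure_id = "exposure", outcome_id = "outcome",
                           extra = NULL) {
  if (anyDuplicated(snp_id)) input_error("snp_id must be unique")
  if (length(snp_id) < 1) estimation_error("no overlapping instruments")
  if (any(exposure_se <= 0) || any(outcome_se <= 0)) {
    input_error("all standard errors must be positive")
  }
  d <- data.frame(snp_id = as.character(snp_id),
                  exposure_beta = exposure_beta,
                  exposure_se = exposure_se,
                  outcome_beta = outcome_beta,
                  outcome_se = outcome_se,
                  stringsAsFactors = FALSE)
  if (!is.null(extra)) d <- cbind(d, extra)
  structure(d,
            exposure_id = exposure_id,
            outcome_id = outcome_id,
            class = c("harmonized_set", "data.frame"))
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s: %d instrument(s)\n",
              attr(x, "exposure_id"), attr(x, "outcome_id"), nrow(x)))
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

n_snp <- function(h) nrow(h)

#' Harmonize exposure and outcome effects to a common effect allele
#'
#' For each SNP shared between the two datasets:
#' \itemize{
#'   \item identical allele pairs are copied;
#'   \item swapped pairs (effect/other exchanged) negate the outcome beta and
#'     replace the outcome EAF by `1 - eaf`;
#'   \item strand-complement pairs are complemented first, then the same rule
#'     applies;
#'   \item palindromic SNPs are dropped when `drop_palindromic` (no
#'     frequency-based rescue is attempted);
#'   \item irreconcilable allele pairs are dropped and counted.
#' }
#' Harmonizing an already-aligned pair is a no-op.
#'
#' @param exposure exposure [summary_dataset()] (typically the selected
#'   instruments).
#' @param outcome outcome [summary_dataset()].
#' @param drop_palindromic drop A/T and C/G SNPs (default `TRUE`).
#' @return A [harmonized_set()] with attributes `n_palindromic_dropped` and
#'   `n_irreconcilable_dropped`. Errors if no SNP is shared.
#' @export
harmonize <- function(exposure, outcome, drop_palindromic = TRUE) {
  idx <- match(exposure$snp_id, outcome$snp_id)
  shared <- !is.na(idx)
  if (!any(shared)) estimation_error("no overlapping instruments")
  e <- as.data.frame(exposure)[shared, , drop = FALSE]
  o <- as.data.frame(outcome)[idx[shared], , drop = FALSE]

  pal <- is_palindromic(e$effect_allele, e$other_allele) |
    is_palindromic(o$effect_allele, o$other_allele)
  drop_pal <- drop_palindromic & pal

  same <- o$effect_allele == e$effect_allele & o$other_allele == e$other_allele
  swapped <- o$effect_allele == e$other_allele & o$other_allele == e$effect_allele
  oc1 <- unname(COMPLEMENT[o$effect_allele])
  oc2 <- unname(COMPLEMENT[o$other_allele])
  comp_same <- oc1 == e$effect_allele & oc2 == e$other_allele
  comp_swapped <- oc1 == e$other_allele & oc2 == e$effect_allele

  # For palindromic SNPs "same" and "comp_swapped" coincide; the palindrome
  # rule above takes precedence when drop_palindromic is set.
  flip <- (swapped | comp_swapped) & !same & !comp_same
  resolvable <- same | swapped | comp_same | comp_swapped
  keep <- resolvable & !drop_pal

  ob <- ifelse(flip, -o$beta, o$beta)
  extra <- data.frame(chrom = e$chrom, pos = e$pos,
                      effect_allele = e$effect_allele,
                      other_allele = e$other_allele,
                      eaf = e$eaf,
                      exposure_pvalue = e$pvalue,
                      outcome_pvalue = o$pvalue,
                      stringsAsFactors = FALSE)

  if (!any(keep)) estimation_error("no overlapping instruments after harmonization")
  h <- harmonized_set(snp_id = e$snp_id[keep],
                      exposure_beta = e$beta[keep],
                      exposure_se = e$se[keep],
                      outcome_beta = ob[keep],
                      outcome_se = o$se[keep],
                      exposure_id = attr(exposure, "trait_id") %||% "exposure",
                      outcome_id = attr(outcome, "trait_id") %||% "outcome",
                      extra = extra[keep, , drop = FALSE])
  attr(h, "n_palindromic_dropped") <- sum(drop_pal & resolvable)
  attr(h, "n_irreconcilable_dropped") <- sum(!resolvable)
  h
}

#' Run the full instrument-selection cascade for one exposure/outcome pair
#'
#' Composes, in order: p-value thresholding, greedy LD clumping, exclusion of
#' outcome-associated SNPs, weak-instrument and MAF filters, and allele
#' harmonization (which drops palindromic SNPs). The per-stage survivor
#' counts are attached as attribute `cascade`.
#'
#' @param exposure,outcome [summary_dataset()] objects.
#' @param ld optional LD matrix.
#' @param config a [mr_config()] list.
#' @param p_threshold instrument threshold; defaults to
#'   `config$iv_p_threshold` (use `config$reverse_iv_p_threshold` for reverse
#'   MR with a disease exposure).
#' @return A [harmonized_set()] ready for estimation.
#' @export
select_instruments <- function(exposure, outcome, ld = NULL,
                               config = mr_config(),
                               p_threshold = config$iv_p_threshold) {
  cand <- threshold_candidates(exposure, p_threshold)
  clumped <- ld_clump(cand, ld, config$clump_r2, config$clump_window_kb)
  kept <- exclude_outcome_associated(clumped, outcome, config$outcome_assoc_p)
  strong <- filter_weak_and_rare(kept, config$f_min, config$maf_min)
  if (nrow(strong) == 0) estimation_error("no instruments survive selection")
  h <- harmonize(strong, outcome, config$drop_palindromic)
  attr(h, "cascade") <- c(candidates = nrow(cand),
                          post_clump = nrow(clumped),
                          post_exclusion = nrow(kept),
                          post_f_maf = nrow(strong),
                          harmonized = nrow(h))
  h
}
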