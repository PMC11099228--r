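# Multivariable IVW: joint weighted regression of outcome effects on the
# effect matrix of several exposures, yielding direct (adjusted) effects.
# In the mediation workflow this supplies the mediator's effect on the
# outcome adjusted for the primary exposure (beta2).

#' Construct a multivariable harmonized set directly
#'
#' @param snp_id character vector of unique SNP ids.
#' @param exposure_betas,exposure_ses numeric matrices (SNP x exposure) with
#'   column names giving the exposure ids.
#' @param outcome_beta,outcome_se outcome-side effects and SEs.
#' @param outcome_id outcome identifier.
#' @return A `multi_harmonized_set` data frame with per-exposure columns
#'   `beta__<id>` / `se__<id>`.
#' @export
multi_harmonized_set <- function(snp_id, exposure_betas, exposure_ses,
                                 outcome_beta, outcome_se,
                                 outcome_id = "outcome") {
  exposure_betas <- as.matrix(exposure_betas)
  exposure_ses <- as.matrix(exposure_ses)
  m <- ncol(exposure_betas)
  if (m < 1) config_error("multivariable MR needs at least 1 exposure")
  ids <- colnames(exposure_betas)
  if (is.null(ids)) config_error("exposure_betas must have exposure ids as column names")
  k <- length(snp_id)
  if (k < m + 1) {
    estimation_error(sprintf(
      "multivariable MR needs at least %d instruments for %d exposures; got %d",
      m + 1, m, k))
  }
  if (anyDuplicated(snp_id)) input_error("snp_id must be unique")
  d <- data.frame(snp_id = as.character(snp_id), stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    d[[paste0("beta__", ids[j])]] <- exposure_betas[, j]
    d[[paste0("se__", ids[j])]] <- exposure_ses[, j]
  }
  d$outcome_beta <- outcome_beta
  d$outcome_se <- outcome_se
  structure(d,
            exposure_ids = ids,
            outcome_id = outcome_id,
            class = c("multi_harmonized_set", "data.frame"))
}

#' @export
print.multi_harmonized_set <- function(x, ...) {
  cat(sprintf("<multi_harmonized_set> {%s} -> %s: %d instrument(s)\n",
              paste(attr(x, "exposure_ids"), collapse = ", "),
              attr(x, "outcome_id"), nrow(x)))
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

mv_design <- function(mh) {
  ids <- attr(mh, "exposure_ids")
  X <- as.matrix(as.data.frame(mh)[, paste0("beta__", ids), drop = FALSE])
  colnames(X) <- ids
  X
}

#' Assemble a jointly harmonized instrument set for multivariable MR
#'
#' The instrument set is the union of the per-exposure instruments (each
#' selected through the univariable cascade of [select_instruments()] minus
#' harmonization), jointly re-clumped by each SNP's best p-value across
#' exposures. Every surviving SNP must be observed in every exposure dataset
#' and the outcome; missing SNPs are dropped and counted in attribute
#' `n_missing_dropped`. All effects are aligned to the first exposure's
#' effect allele, with palindromic SNPs dropped when the configuration says
#' so.
#'
#' @param exposures named list of at least two [summary_dataset()] objects;
#'   names are the exposure ids (defaults to their trait ids).
#' @param outcome outcome [summary_dataset()].
#' @param ld optional LD matrix.
#' @param config a [mr_config()].
#' @return A [multi_harmonized_set()].
#' @export
assemble_mv_set <- function(exposures, outcome, ld = NULL,
                            config = mr_config()) {
  if (length(exposures) < 2) config_error("need at least 2 exposures")
  ids <- names(exposures)
  if (is.null(ids)) {
    ids <- vapply(exposures, function(d) attr(d, "trait_id") %||% "exposure",
                  character(1))
    names(exposures) <- ids
  }
  if (anyDuplicated(ids)) config_error("exposure ids must be unique")

  per_exposure <- lapply(exposures, function(ds) {
    cand <- threshold_candidates(ds, config$iv_p_threshold)
    clumped <- ld_clump(cand, ld, config$clump_r2, config$clump_window_kb)
    kept <- exclude_outcome_associated(clumped, outcome, config$outcome_assoc_p)
    filter_weak_and_rare(kept, config$f_min, config$maf_min)
  })
  union_ids <- unique(unlist(lapply(per_exposure, function(d) d$snp_id)))
  if (length(union_ids) == 0) estimation_error("no instruments survive selection")

  # Joint re-clump of the union by best p-value across exposures.
  best <- do.call(rbind, lapply(exposures, function(ds) {
    as.data.frame(ds)[ds$snp_id %in% union_ids, , drop = FALSE]
  }))
  best <- best[order(best$pvalue), , drop = FALSE]
  best <- best[!duplicated(best$snp_id), , drop = FALSE]
  union_ds <- summary_dataset(best, trait_id = "mv_union", quiet = TRUE)
  union_ds <- ld_clump(union_ds, ld, config$clump_r2, config$clump_window_kb)

  # Reference orientation: the first exposure's record per SNP.
  ref <- exposures[[1]]
  ref_idx <- match(union_ds$snp_id, ref$snp_id)
  present <- !is.na(ref_idx)
  align_to_ref <- function(ds, ref_rows) {
    idx <- match(ref_rows$snp_id, ds$snp_id)
    hit <- !is.na(idx)
    beta <- se <- rep(NA_real_, nrow(ref_rows))
    d <- as.data.frame(ds)[idx[hit], , drop = FALSE]
    r <- ref_rows[hit, , drop = FALSE]
    same <- d$effect_allele == r$effect_allele & d$other_allele == r$other_allele
    swapped <- d$effect_allele == r$other_allele & d$other_allele == r$effect_allele
    c1 <- unname(COMPLEMENT[d$effect_allele])
    c2 <- unname(COMPLEMENT[d$other_allele])
    comp_same <- c1 == r$effect_allele & c2 == r$other_allele
    comp_swapped <- c1 == r$other_allele & c2 == r$effect_allele
    flip <- (swapped | comp_swapped) & !same & !comp_same
    resolvable <- same | swapped | comp_same | comp_swapped
    beta[hit][resolvable] <- ifelse(flip[resolvable], -d$beta[resolvable],
                                    d$beta[resolvable])
    se[hit][resolvable] <- d$se[resolvable]
    list(beta = beta, se = se)
  }

  ref_rows <- as.data.frame(ref)[ref_idx[present], , drop = FALSE]
  snps <- union_ds$snp_id[present]
  ref_rows <- ref_rows[match(snps, ref_rows$snp_id), , drop = FALSE]
  pal <- is_palindromic(ref_rows$effect_allele, ref_rows$other_allele)

  m <- length(exposures)
  B <- matrix(NA_real_, nrow = length(snps), ncol = m, dimnames = list(NULL, ids))
  S <- B
  for (j in seq_len(m)) {
    al <- align_to_ref(exposures[[j]], ref_rows)
    B[, j] <- al$beta
    S[, j] <- al$se
  }
  alo <- align_to_ref(outcome, ref_rows)

  complete <- stats::complete.cases(B) & stats::complete.cases(S) &
    !is.na(alo$beta) & !is.na(alo$se)
  if (config$drop_palindromic) complete <- complete & !pal
  n_missing <- sum(!complete)
  if (sum(complete) < m + 1) {
    estimation_error(sprintf(
      "multivariable MR needs at least %d instruments; %d remain after assembly",
      m + 1, sum(complete)))
  }
  mh <- multi_harmonized_set(snps[complete],
                             B[complete, , drop = FALSE],
                             S[complete, , drop = FALSE],
                             alo$beta[complete], alo$se[complete],
                             outcome_id = attr(outcome, "trait_id") %||% "outcome")
  attr(mh, "n_missing_dropped") <- n_missing
  mh
}

#' Multivariable IVW estimation
#'
#' Weighted least squares of outcome effects on the matrix of exposure
#' effects, weights `1/outcome_se^2`, no intercept. Per-coefficient standard
#' errors carry a multiplicative overdispersion factor bounded below by 1;
#' p-values use the t-distribution with `k - m` degrees of freedom.
#'
#' @param mh a [multi_harmonized_set()].
#' @return Named list of [mr_estimate()] objects, one per exposure, each with
#'   `extra$adjusted_for` naming its co-exposures.
#' @export
mv_ivw <- function(mh) {
  ids <- attr(mh, "exposure_ids")
  m <- length(ids)
  k <- nrow(mh)
  X <- mv_design(mh)
  G <- mh$outcome_beta
  w <- 1 / mh$outcome_se^2
  Xw <- X * sqrt(w)
  if (qr(Xw)$rank < m) {
    estimation_error(paste0("rank-deficient design (collinear exposures): ",
                            paste(ids, collapse = ", ")))
  }
  fit <- stats::lm.wfit(x = X, y = G, w = w)
  coefs <- fit$coefficients
  res <- fit$residuals
  sigma2 <- sum(w * res^2) / (k - m)
  scale2 <- max(1, sigma2)  # overdispersion never shrinks below fixed-effect
  XtWX_inv <- chol2inv(chol(crossprod(Xw)))
  ses <- sqrt(diag(XtWX_inv) * scale2)
  out <- vector("list", m)
  names(out) <- ids
  for (j in seq_len(m)) {
    p <- 2 * stats::pt(-abs(coefs[j] / ses[j]), df = k - m)
    out[[j]] <- mr_estimate("mv_ivw", unname(coefs[j]), ses[j], p, k,
                            extra = list(exposure = ids[j],
                                         adjusted_for = setdiff(ids, ids[j]),
                                         sigma2 = sigma2))
  }
  out
}
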