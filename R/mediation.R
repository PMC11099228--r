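# Four-step mediator screen and product-of-coefficients mediation
# quantification:
#   step 1  exposure -> mediator UVMR (beta1), significant and pleiotropy-free
#   step 2  mediator -> outcome UVMR (alpha), significant and pleiotropy-free
#   step 3  sign consistency: sign(beta1 * alpha) == sign(beta_total)
#   step 4  mediator -> outcome MVMR adjusted for the exposure (beta2),
#           retained iff its p-value < alpha
# Mediated effect = beta1 * beta2; proportion = (beta1 * beta2) / beta_total.

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the input.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return Vector of q-values aligned with `pvalues`.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    input_error("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Sign-consistency rule for a candidate mediator pathway
#'
#' TRUE iff `sign(beta1 * alpha) == sign(beta_total)`: when the total effect
#' is positive the two legs must share a sign; when negative they must
#' differ.
#'
#' @param beta_total total exposure -> outcome effect.
#' @param beta1 exposure -> mediator effect.
#' @param alpha mediator -> outcome (univariable) effect.
#' @return Logical scalar. A zero argument is a screening error (direction
#'   undefined).
#' @export
sign_consistent <- function(beta_total, beta1, alpha) {
  if (beta_total == 0 || beta1 == 0 || alpha == 0) {
    screening_error("sign consistency undefined for a zero effect")
  }
  sign(beta1 * alpha) == sign(beta_total)
}

#' Product-of-coefficients mediated effect and proportion
#'
#' `mediated = beta1 * beta2`; `proportion = mediated / beta_total` (log-OR
#' scale, not ORs). The confidence interval for the mediated effect uses the
#' delta-method variance `beta2^2 se1^2 + beta1^2 se2^2`; the proportion CI
#' scales it by `beta_total`.
#'
#' @param beta_total total exposure -> outcome effect (non-zero).
#' @param beta1 exposure -> mediator effect and `se_beta1` its SE.
#' @param beta2 adjusted mediator -> outcome effect and `se_beta2` its SE.
#' @param se_beta1,se_beta2 standard errors.
#' @return List with `mediated`, `se_mediated`, `ci_mediated`, `proportion`,
#'   `ci_proportion`, and the delta-method `p_mediated` (an extension; the
#'   screen's reported mediation p is the multivariable p of `beta2`).
#' @export
mediation_effect <- function(beta_total, beta1, beta2, se_beta1, se_beta2) {
  if (beta_total == 0) {
    screening_error("mediation proportion undefined when the total effect is zero")
  }
  mediated <- beta1 * beta2
  se_med <- sqrt(beta2^2 * se_beta1^2 + beta1^2 * se_beta2^2)
  ci_med <- c(mediated - Z975 * se_med, mediated + Z975 * se_med)
  proportion <- mediated / beta_total
  ci_prop <- sort(ci_med / beta_total)
  list(mediated = mediated,
       se_mediated = se_med,
       ci_mediated = ci_med,
       proportion = proportion,
       ci_proportion = ci_prop,
       p_mediated = z_to_p(mediated / se_med))
}

# Shared screening leg: UVMR of `exposure` on `outcome_ds` with IVW primary
# plus pleiotropy flags (Egger intercept; MR-PRESSO when configured).
screen_leg <- function(exposure, outcome_ds, ld, config,
                       p_threshold = config$iv_p_threshold) {
  h <- select_instruments(exposure, outcome_ds, ld, config, p_threshold)
  est <- if (nrow(h) == 1) wald_ratio(h) else mr_ivw(h)
  egger_p <- if (nrow(h) >= 3) egger_intercept_test(h)$pvalue else NA_real_
  presso_p <- NA_real_
  if (isTRUE(config$use_presso) && nrow(h) >= 4) {
    presso_p <- mr_presso(h, config$presso_n_sim, config$presso_outlier_p,
                          config$seed)$global_p
  }
  pleiotropy <- (!is.na(egger_p) && egger_p < config$alpha) ||
    (!is.na(presso_p) && presso_p < config$alpha)
  list(h = h, estimate = est, egger_intercept_p = egger_p,
       presso_global_p = presso_p, pleiotropy_flag = pleiotropy)
}

screen_many <- function(exposure_fn, ids, config) {
  rows <- lapply(ids, function(id) {
    leg <- tryCatch(exposure_fn(id), axismr_error = function(e) NULL)
    if (is.null(leg)) {
      return(data.frame(id = id, beta = NA_real_, se = NA_real_,
                        pvalue = NA_real_, n_snp = NA_integer_,
                        egger_intercept_p = NA_real_,
                        presso_global_p = NA_real_,
                        pleiotropy_flag = NA, retained = FALSE,
                        reason = "no_instruments", stringsAsFactors = FALSE))
    }
    est <- leg$estimate
    retained <- est$pvalue < config$alpha && !leg$pleiotropy_flag
    reason <- if (retained) "retained"
      else if (leg$pleiotropy_flag) "pleiotropy" else "not_significant"
    data.frame(id = id, beta = est$beta, se = est$se, pvalue = est$pvalue,
               n_snp = est$n_snp, egger_intercept_p = leg$egger_intercept_p,
               presso_global_p = leg$presso_global_p,
               pleiotropy_flag = leg$pleiotropy_flag, retained = retained,
               reason = reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Step 1: screen mediators causally influenced by the exposure
#'
#' Univariable IVW of the exposure on each candidate mediator; a mediator is
#' retained when the IVW p-value is below `config$alpha` and no pleiotropy
#' flag is raised (Egger intercept test; MR-PRESSO when
#' `config$use_presso`).
#'
#' @param exposure exposure [summary_dataset()].
#' @param mediators named list of mediator [summary_dataset()] objects.
#' @param ld optional LD matrix.
#' @param config a [mr_config()].
#' @return Data frame with one row per mediator: `id`, `beta` (beta1), `se`,
#'   `pvalue`, pleiotropy diagnostics, `retained`, `reason`.
#' @export
screen_exposure_to_mediator <- function(exposure, mediators, ld = NULL,
                                        config = mr_config()) {
  mediators <- name_datasets(mediators)
  screen_many(function(id) screen_leg(exposure, mediators[[id]], ld, config),
              names(mediators), config)
}

#' Step 2: screen mediators causally affecting the outcome
#'
#' As step 1 with each mediator as the exposure side and the disease outcome
#' as the outcome; returns alpha estimates.
#'
#' @param mediators named list of mediator [summary_dataset()] objects.
#' @param outcome outcome [summary_dataset()].
#' @inheritParams screen_exposure_to_mediator
#' @return Data frame as in [screen_exposure_to_mediator()], `beta` holding
#'   alpha.
#' @export
screen_mediator_to_outcome <- function(mediators, outcome, ld = NULL,
                                       config = mr_config()) {
  mediators <- name_datasets(mediators)
  screen_many(function(id) screen_leg(mediators[[id]], outcome, ld, config),
              names(mediators), config)
}

#' Step 4: adjusted mediator effect via multivariable IVW
#'
#' Fits MV-IVW with exposures (mediator, primary exposure) on the outcome and
#' returns the mediator's coefficient (beta2).
#'
#' @param exposure primary exposure [summary_dataset()].
#' @param mediator mediator [summary_dataset()].
#' @param outcome outcome [summary_dataset()].
#' @param ld optional LD matrix.
#' @param config a [mr_config()].
#' @return An [mr_estimate()] for the mediator, adjusted for the exposure.
#' @export
adjusted_mediator_effect <- function(exposure, mediator, outcome, ld = NULL,
                                     config = mr_config()) {
  exposures <- list(mediator, exposure)
  names(exposures) <- c(trait_id(mediator), trait_id(exposure))
  mh <- assemble_mv_set(exposures, outcome, ld, config)
  mv_ivw(mh)[[1]]
}

#' Estimate the mediation decomposition for one (exposure, mediator, outcome)
#'
#' Runs the quantification core: beta_total (UVMR IVW exposure -> outcome),
#' beta1 (UVMR exposure -> mediator), alpha (UVMR mediator -> outcome),
#' beta2 (MV-IVW mediator -> outcome adjusted for the exposure), and the
#' product-of-coefficients mediated effect and proportion. Step pass flags
#' are recorded; the candidate is `retained` when all four hold.
#'
#' @inheritParams adjusted_mediator_effect
#' @param beta_total optionally a precomputed [mr_estimate()] of the total
#'   effect, to avoid refitting inside loops.
#' @return One-row data frame with effects, SEs, p-values, `mediated_effect`,
#'   `proportion`, `proportion_ci_low/high`, `passed_steps`, `retained`, and
#'   an `inconsistent_mediation` flag for proportions outside \[0, 1\].
#' @export
estimate_mediation <- function(exposure, mediator, outcome, ld = NULL,
                               config = mr_config(), beta_total = NULL) {
  s1 <- screen_leg(exposure, mediator, ld, config)
  s2 <- screen_leg(mediator, outcome, ld, config)
  if (is.null(beta_total)) {
    beta_total <- screen_leg(exposure, outcome, ld, config)$estimate
  }
  b <- beta_total$beta
  b1 <- s1$estimate$beta
  a <- s2$estimate$beta

  pass1 <- s1$estimate$pvalue < config$alpha && !s1$pleiotropy_flag
  pass2 <- s2$estimate$pvalue < config$alpha && !s2$pleiotropy_flag
  pass_sign <- b != 0 && b1 != 0 && a != 0 && sign_consistent(b, b1, a)

  b2_est <- tryCatch(
    adjusted_mediator_effect(exposure, mediator, outcome, ld, config),
    axismr_error = function(e) NULL)
  pass4 <- !is.null(b2_est) && b2_est$pvalue < config$alpha

  b2 <- if (is.null(b2_est)) NA_real_ else b2_est$beta
  se_b2 <- if (is.null(b2_est)) NA_real_ else b2_est$se
  med <- if (!is.null(b2_est) && b != 0) {
    mediation_effect(b, b1, b2, s1$estimate$se, se_b2)
  } else NULL

  passed <- c("step1", "step2", "sign", "step4")[c(pass1, pass2, pass_sign, pass4)]
  data.frame(
    exposure_id = trait_id(exposure),
    mediator_id = trait_id(mediator),
    outcome_id = trait_id(outcome),
    beta_total = b, se_total = beta_total$se, p_total = beta_total$pvalue,
    beta1 = b1, se_beta1 = s1$estimate$se, p_beta1 = s1$estimate$pvalue,
    alpha = a, se_alpha = s2$estimate$se, p_alpha = s2$estimate$pvalue,
    beta2 = b2, se_beta2 = se_b2,
    p_mediator = if (is.null(b2_est)) NA_real_ else b2_est$pvalue,
    mediated_effect = if (is.null(med)) NA_real_ else med$mediated,
    proportion = if (is.null(med)) NA_real_ else med$proportion,
    proportion_ci_low = if (is.null(med)) NA_real_ else med$ci_proportion[1],
    proportion_ci_high = if (is.null(med)) NA_real_ else med$ci_proportion[2],
    passed_steps = paste(passed, collapse = ","),
    retained = pass1 && pass2 && pass_sign && pass4,
    inconsistent_mediation = !is.null(med) &&
      (med$proportion < 0 || abs(med$proportion) > 1),
    stringsAsFactors = FALSE
  )
}

#' Run the full four-step mediation screen
#'
#' For every exposure-outcome pair whose total-effect UVMR is significant
#' (IVW p below `config$alpha`), evaluates every mediator through steps 1-4
#' and the product-of-coefficients decomposition. Candidates with a
#' proportion outside \[0, 1\] are retained but flagged
#' `inconsistent_mediation`.
#'
#' @param exposures,mediators,outcomes named lists of [summary_dataset()]
#'   objects.
#' @param ld optional LD matrix.
#' @param config a [mr_config()].
#' @param eligible_pairs optional data frame with columns
#'   `exposure_id`/`outcome_id` restricting the pairs to screen (e.g. after
#'   reverse-causality exclusion).
#' @return List with `results` (retained pathways) and `audit` (every
#'   evaluated candidate with its step flags).
#' @export
run_mediation_screen <- function(exposures, mediators, outcomes, ld = NULL,
                                 config = mr_config(),
                                 eligible_pairs = NULL) {
  exposures <- name_datasets(exposures)
  mediators <- name_datasets(mediators)
  outcomes <- name_datasets(outcomes)

  audit <- list()
  for (eid in names(exposures)) {
    for (oid in names(outcomes)) {
      if (!is.null(eligible_pairs) &&
          !any(eligible_pairs$exposure_id == eid &
               eligible_pairs$outcome_id == oid)) next
      total <- tryCatch(
        screen_leg(exposures[[eid]], outcomes[[oid]], ld, config),
        axismr_error = function(e) NULL)
      if (is.null(total)) next
      if (total$estimate$pvalue >= config$alpha || total$pleiotropy_flag) next
      for (mid in names(mediators)) {
        row <- tryCatch(
          estimate_mediation(exposures[[eid]], mediators[[mid]],
                             outcomes[[oid]], ld, config,
                             beta_total = total$estimate),
          axismr_error = function(e) NULL)
        if (!is.null(row)) audit[[length(audit) + 1]] <- row
      }
    }
  }
  audit <- if (length(audit)) do.call(rbind, audit) else
    data.frame()
  results <- if (nrow(audit)) audit[audit$retained, , drop = FALSE] else audit
  rownames(results) <- NULL
  list(results = results, audit = audit)
}

#' Apply the step-4 retention rule to a precomputed candidate table
#'
#' Fixture-injection mode: given a table of candidate mediator pathways with
#' their univariable and multivariable estimates already computed (columns
#' `outcome`, `mediator`, `uvmr_p`, `adjust_for`, `mvmr_beta`, `mvmr_p`),
#' retains the rows whose multivariable p-value is below `alpha` and counts
#' the distinct mediator phenotypes among them. Mediator names are compared
#' case-insensitively.
#'
#' @param candidates data frame of candidate rows.
#' @param alpha retention threshold (default 0.05).
#' @return List with `retained` (the retained rows), `n_pathways`, and
#'   `n_mediators`.
#' @export
apply_retention_rule <- function(candidates, alpha = 0.05) {
  needed <- c("outcome", "mediator", "mvmr_p")
  missing_cols <- setdiff(needed, names(candidates))
  if (length(missing_cols)) {
    config_error(paste0("candidate table missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  keep <- candidates$mvmr_p < alpha
  retained <- candidates[keep, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained,
       n_pathways = nrow(retained),
       n_mediators = length(unique(tolower(retained$mediator))))
}

#' Bundled candidate mediator table
#'
#' A published 20-row screen of candidate immune-cell mediator pathways for
#' gut-microbiota exposures on lung-cancer subtypes: per row the outcome, the
#' immune-cell mediator, its univariable OR (95% CI) and IVW p-value, the
#' microbial taxon adjusted for, and the multivariable (adjusted) beta with
#' 95% CI and p-value. Used to exercise the retention logic of
#' [apply_retention_rule()] without external GWAS downloads.
#'
#' @return Data frame with 20 rows.
#' @export
example_candidate_screen <- function() {
  path <- system.file("extdata", "mediator_candidates.tsv", package = "axismr",
                      mustWork = TRUE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = TRUE)
}
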