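# Robustness layer: Cochran's Q heterogeneity, Egger intercept pleiotropy
# test, MR-PRESSO global/outlier/distortion tests, and leave-one-out IVW.

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_j (b_j - b_ivw)^2)` over Wald ratios `b_j` with weights
#' `w_j = exposure_beta^2 / outcome_se^2`, referred to a chi-square with
#' `k - 1` degrees of freedom.
#'
#' @param h a [harmonized_set()] with at least two variants.
#' @return List with `q`, `df`, `pvalue`.
#' @export
cochran_q <- function(h) {
  k <- nrow(h)
  if (k < 2) estimation_error("Cochran's Q needs at least 2 instruments")
  wc <- wald_components(h)
  b_ivw <- sum(wc$weight * wc$ratio) / sum(wc$weight)
  q <- sum(wc$weight * (wc$ratio - b_ivw)^2)
  list(q = q, df = k - 1L,
       pvalue = stats::pchisq(q, k - 1, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Returns the Egger regression intercept and its two-sided t p-value
#' (`k - 2` df). A small p-value indicates directional horizontal
#' pleiotropy, which invalidates the IVW causal claim.
#'
#' @param h a [harmonized_set()] with at least three variants.
#' @return List with `intercept`, `se`, `pvalue`.
#' @export
egger_intercept_test <- function(h) {
  e <- mr_egger(h)
  list(intercept = e$extra$egger_intercept,
       se = e$extra$egger_intercept_se,
       pvalue = e$extra$egger_intercept_p)
}

# Leave-one-out IVW slopes from running sums; vectorized over SNPs.
loo_ivw_slopes <- function(g, G, w) {
  s_gG <- sum(w * g * G)
  s_gg <- sum(w * g^2)
  (s_gG - w * g * G) / (s_gg - w * g^2)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Simulation-based detection of pleiotropic outlier instruments.
#' \itemize{
#'   \item Global test: the observed residual sum of squares
#'     `sum_j w_j (G_j - b_(-j) g_j)^2` (with `b_(-j)` the leave-one-out IVW
#'     slope and `w = 1/outcome_se^2`) is compared with its distribution
#'     under `n_sim` parametric simulations drawing
#'     `g* ~ N(g, exposure_se)` and `G* ~ N(b_(-j) g, outcome_se)`.
#'   \item Outlier test: each SNP's observed weighted squared residual is
#'     ranked against its simulated counterparts; per-SNP p-values are
#'     compared with `outlier_p / k` (Bonferroni).
#'   \item Distortion test: when outliers exist, the percentage shift
#'     between the all-SNP and outlier-removed IVW estimates is compared
#'     with the shifts induced by removing 1,000 random same-size SNP
#'     subsets.
#' }
#'
#' @param h a [harmonized_set()] with at least four variants.
#' @param n_sim number of parametric simulations (>= 100; default 1000).
#' @param outlier_p outlier significance level before Bonferroni (default
#'   0.05).
#' @param seed integer seed; results are reproducible bit for bit.
#' @return An object of class `mr_presso`: list with `global_rss`,
#'   `global_p` (numeric; equal to `1/n_sim` with `global_p_bound = TRUE`
#'   when no simulated RSS reaches the observed one), `outliers`,
#'   `outlier_pvalues`, `distortion_p`, and `estimate_outlier_corrected`
#'   (IVW without the flagged SNPs, `NULL` when none).
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_p = 0.05, seed = 1L) {
  k <- nrow(h)
  if (k < 4) estimation_error("MR-PRESSO needs at least 4 instruments")
  if (n_sim < 100) config_error("n_sim must be at least 100")
  g <- h$exposure_beta
  G <- h$outcome_beta
  seg <- h$exposure_se
  seG <- h$outcome_se
  w <- 1 / seG^2
  b_loo <- loo_ivw_slopes(g, G, w)
  resid_obs <- w * (G - b_loo * g)^2
  rss_obs <- sum(resid_obs)

  sim <- with_seed(seed, {
    gs <- matrix(stats::rnorm(n_sim * k, rep(g, each = n_sim),
                              rep(seg, each = n_sim)), nrow = n_sim)
    Gs <- matrix(stats::rnorm(n_sim * k, rep(b_loo * g, each = n_sim),
                              rep(seG, each = n_sim)), nrow = n_sim)
    W <- matrix(w, nrow = n_sim, ncol = k, byrow = TRUE)
    s_gG <- as.vector((gs * Gs * W) %*% rep(1, k))
    s_gg <- as.vector((gs^2 * W) %*% rep(1, k))
    b_loo_s <- (s_gG - W * gs * Gs) / (s_gg - W * gs^2)
    res_s <- W * (Gs - b_loo_s * gs)^2
    list(res = res_s, rss = as.vector(res_s %*% rep(1, k)))
  })

  n_ge <- sum(sim$rss >= rss_obs)
  global_p_bound <- n_ge == 0
  global_p <- if (global_p_bound) 1 / n_sim else n_ge / n_sim

  outlier_pvalues <- colMeans(sim$res >= matrix(resid_obs, nrow = n_sim,
                                                ncol = k, byrow = TRUE))
  names(outlier_pvalues) <- h$snp_id
  is_out <- outlier_pvalues < outlier_p / k
  outliers <- h$snp_id[is_out]

  distortion_p <- NA_real_
  est_corr <- NULL
  if (length(outliers) > 0 && k - length(outliers) >= 2) {
    keep <- !is_out
    hk <- h[keep, , drop = FALSE]
    class(hk) <- class(h)
    attr(hk, "exposure_id") <- attr(h, "exposure_id")
    attr(hk, "outcome_id") <- attr(h, "outcome_id")
    est_corr <- mr_ivw(hk)
    b_all <- sum(w * g * G) / sum(w * g^2)
    b_no <- est_corr$beta
    d_obs <- 100 * (b_all - b_no) / abs(b_no)
    n_out <- length(outliers)
    d_sim <- with_seed(seed + 1L, {
      vapply(seq_len(1000), function(i) {
        drop_idx <- sample.int(k, n_out)
        sel <- setdiff(seq_len(k), drop_idx)
        b_i <- sum(w[sel] * g[sel] * G[sel]) / sum(w[sel] * g[sel]^2)
        100 * (b_all - b_i) / abs(b_i)
      }, numeric(1))
    })
    distortion_p <- mean(abs(d_sim) >= abs(d_obs))
  }

  structure(list(global_rss = rss_obs,
                 global_p = global_p,
                 global_p_bound = global_p_bound,
                 n_sim = n_sim,
                 outliers = outliers,
                 outlier_pvalues = outlier_pvalues,
                 distortion_p = distortion_p,
                 estimate_outlier_corrected = est_corr),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  p_str <- if (x$global_p_bound) paste0("< ", format(1 / x$n_sim)) else format(x$global_p)
  cat(sprintf("<mr_presso> global RSS %.4g (p %s); %d outlier(s)%s\n",
              x$global_rss, p_str, length(x$outliers),
              if (length(x$outliers)) paste0(": ", paste(x$outliers, collapse = ", ")) else ""))
  invisible(x)
}

#' Leave-one-out IVW analysis
#'
#' Refits IVW `k` times, omitting each instrument in turn (input order).
#'
#' @param h a [harmonized_set()] with at least three variants.
#' @param model IVW variant passed to [mr_ivw()].
#' @return Data frame with one row per left-out SNP: `snp_id_left_out`,
#'   `beta`, `se`, `pvalue`, `n_snp`.
#' @export
leave_one_out <- function(h, model = "multiplicative_random") {
  k <- nrow(h)
  if (k < 3) estimation_error("leave-one-out needs at least 3 instruments")
  rows <- lapply(seq_len(k), function(j) {
    hj <- h[-j, , drop = FALSE]
    class(hj) <- class(h)
    est <- mr_ivw(hj, model)
    data.frame(snp_id_left_out = h$snp_id[j], beta = est$beta, se = est$se,
               pvalue = est$pvalue, n_snp = est$n_snp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full sensitivity report for one exposure-outcome pair
#'
#' Combines Cochran's Q, the Egger intercept test, MR-PRESSO, and
#' leave-one-out, and derives the decision flags: heterogeneity when
#' `P_heterogeneity < alpha`; pleiotropy when the Egger intercept p or the
#' MR-PRESSO global p falls below `alpha`. Evidence of pleiotropy
#' invalidates the causal claim for the pair.
#'
#' @param h a [harmonized_set()] with at least four variants.
#' @param config a [mr_config()] (alpha, PRESSO settings, seed).
#' @return An object of class `sensitivity_report`.
#' @export
sensitivity_report <- function(h, config = mr_config()) {
  q <- cochran_q(h)
  eg <- egger_intercept_test(h)
  pr <- mr_presso(h, config$presso_n_sim, config$presso_outlier_p, config$seed)
  structure(list(
    q_statistic = q$q,
    q_df = q$df,
    p_heterogeneity = q$pvalue,
    egger_intercept = eg$intercept,
    p_pleiotropy = eg$pvalue,
    presso_global_p = pr$global_p,
    presso_global_p_bound = pr$global_p_bound,
    presso_outliers = pr$outliers,
    presso_distortion_p = pr$distortion_p,
    loo = leave_one_out(h),
    heterogeneity_flag = q$pvalue < config$alpha,
    pleiotropy_flag = (eg$pvalue < config$alpha) || (pr$global_p < config$alpha)
  ), class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> Q %.3g (df %d, p %.3g)%s\n",
              x$q_statistic, x$q_df, x$p_heterogeneity,
              if (x$heterogeneity_flag) " [heterogeneity]" else ""))
  cat(sprintf("  egger intercept %.3g (p %.3g); presso global p %s%s\n",
              x$egger_intercept, x$p_pleiotropy,
              if (x$presso_global_p_bound) paste0("< ", format(x$presso_global_p))
              else format(x$presso_global_p),
              if (x$pleiotropy_flag) " [pleiotropy: causal claim invalid]" else ""))
  invisible(x)
}

#' Tidy a sensitivity report into a one-row data frame
#'
#' @param x a [sensitivity_report()].
#' @param ... unused.
#' @return One-row data frame matching the sensitivity TSV schema.
#' @export
as.data.frame.sensitivity_report <- function(x, ...) {
  data.frame(q = x$q_statistic, q_df = x$q_df,
             p_heterogeneity = x$p_heterogeneity,
             egger_intercept = x$egger_intercept,
             p_pleiotropy = x$p_pleiotropy,
             presso_global_p = x$presso_global_p,
             presso_global_p_bound = x$presso_global_p_bound,
             presso_outliers = paste(x$presso_outliers, collapse = ";"),
             presso_distortion_p = x$presso_distortion_p,
             heterogeneity_flag = x$heterogeneity_flag,
             pleiotropy_flag = x$pleiotropy_flag,
             stringsAsFactors = FALSE)
}
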