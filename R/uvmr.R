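# Univariable two-sample MR estimators on a harmonized set: Wald ratio,
# inverse-variance weighted (IVW), MR-Egger, weighted median, and mode-based
# (weighted and simple).

#' Construct an MR estimate object
#'
#' @param method estimator name.
#' @param beta causal effect estimate (log odds ratio for binary outcomes,
#'   SD units for continuous ones).
#' @param se standard error.
#' @param pvalue two-sided p-value.
#' @param n_snp number of instruments.
#' @param extra optional named list of method-specific quantities (e.g. the
#'   Egger intercept and its p-value).
#' @return An object of class `mr_estimate` with normal 95% confidence
#'   limits `ci_low`/`ci_high` and `odds_ratio = exp(beta)`.
#' @export
mr_estimate <- function(method, beta, se, pvalue, n_snp, extra = list()) {
  if (se < 0) estimation_error("negative standard error")
  structure(list(method = method,
                 beta = beta,
                 se = se,
                 ci_low = beta - Z975 * se,
                 ci_high = beta + Z975 * se,
                 pvalue = pvalue,
                 odds_ratio = exp(beta),
                 n_snp = as.integer(n_snp),
                 extra = extra),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s: beta %.4g (se %.4g), OR %.4g [%.4g, %.4g], p %.3g, %d SNP(s)\n",
              x$method, x$beta, x$se, x$odds_ratio, exp(x$ci_low),
              exp(x$ci_high), x$pvalue, x$n_snp))
  if (!is.null(x$extra$egger_intercept)) {
    cat(sprintf("  egger intercept %.4g (p %.3g)\n",
                x$extra$egger_intercept, x$extra$egger_intercept_p))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snp = x$n_snp, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pvalue = x$pvalue,
             odds_ratio = x$odds_ratio,
             egger_intercept = x$extra$egger_intercept %||% NA_real_,
             egger_intercept_p = x$extra$egger_intercept_p %||% NA_real_,
             stringsAsFactors = FALSE)
}

wald_components <- function(h) {
  if (any(h$exposure_beta == 0)) {
    estimation_error("exposure effect of zero: Wald ratio undefined")
  }
  list(ratio = h$outcome_beta / h$exposure_beta,
       # first-order delta approximation to the ratio SE
       se = h$outcome_se / abs(h$exposure_beta),
       weight = h$exposure_beta^2 / h$outcome_se^2)
}

#' Wald ratio estimate for a single instrument
#'
#' `beta = outcome_beta / exposure_beta` with first-order standard error
#' `outcome_se / |exposure_beta|` and a normal p-value.
#'
#' @param h a [harmonized_set()] with exactly one variant (or the row to use).
#' @return An [mr_estimate()].
#' @export
wald_ratio <- function(h) {
  if (nrow(h) != 1) estimation_error("wald_ratio expects exactly one variant")
  wc <- wald_components(h)
  mr_estimate("wald", wc$ratio, wc$se, z_to_p(wc$ratio / wc$se), 1L)
}

#' Inverse-variance weighted estimate
#'
#' Weighted zero-intercept regression of outcome effects on exposure effects
#' with weights `1/outcome_se^2`:
#' `beta = sum(w g G) / sum(w g^2)` where `g`/`G` are exposure/outcome
#' effects. The fixed-effect SE is `1/sqrt(sum(w g^2))`; the multiplicative
#' random-effects model (default) scales it by `max(1, sqrt(Q/(k-1)))` where
#' `Q` is Cochran's statistic, so it never undershoots the fixed model.
#' P-values use the normal reference.
#'
#' @param h a [harmonized_set()] with at least two variants.
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An [mr_estimate()] with `Q`, `Q_df`, `Q_pvalue` in `extra`.
#' @export
mr_ivw <- function(h, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  k <- nrow(h)
  if (k < 2) {
    estimation_error("IVW needs at least 2 instruments; use wald_ratio()")
  }
  g <- h$exposure_beta
  G <- h$outcome_beta
  w <- 1 / h$outcome_se^2
  denom <- sum(w * g^2)
  beta <- sum(w * g * G) / denom
  se_fixed <- 1 / sqrt(denom)
  Q <- sum(w * (G - beta * g)^2)
  se <- if (model == "multiplicative_random") {
    se_fixed * max(1, sqrt(Q / (k - 1)))
  } else {
    se_fixed
  }
  mr_estimate("ivw", beta, se, z_to_p(beta / se), k,
              extra = list(model = model, Q = Q, Q_df = k - 1L,
                           Q_pvalue = stats::pchisq(Q, k - 1, lower.tail = FALSE)))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with a free
#' intercept, after reorienting every instrument so its exposure effect is
#' non-negative. A non-zero intercept indicates directional horizontal
#' pleiotropy. Standard errors carry a multiplicative overdispersion factor
#' bounded below by 1; p-values use the t-distribution with `k - 2` degrees
#' of freedom for both slope and intercept.
#'
#' @param h a [harmonized_set()] with at least three variants.
#' @return An [mr_estimate()] whose `extra` holds `egger_intercept`,
#'   `egger_intercept_se`, `egger_intercept_p`, and the overdispersion
#'   `sigma`.
#' @export
mr_egger <- function(h) {
  k <- nrow(h)
  if (k < 3) estimation_error("MR-Egger needs at least 3 instruments")
  s <- ifelse(h$exposure_beta < 0, -1, 1)
  g <- h$exposure_beta * s
  G <- h$outcome_beta * s
  w <- 1 / h$outcome_se^2
  fit <- stats::lm(G ~ g, weights = w)
  sm <- suppressWarnings(summary(fit))  # exact fits warn harmlessly
  sigma <- sm$sigma
  scale <- 1 / min(1, sigma)  # enforce overdispersion factor >= 1
  b <- unname(stats::coef(fit)[2])
  se_b <- sm$coefficients[2, 2] * scale
  a0 <- unname(stats::coef(fit)[1])
  se_a0 <- sm$coefficients[1, 2] * scale
  p_b <- 2 * stats::pt(-abs(b / se_b), df = k - 2)
  p_a0 <- 2 * stats::pt(-abs(a0 / se_a0), df = k - 2)
  mr_estimate("egger", b, se_b, p_b, k,
              extra = list(egger_intercept = a0,
                           egger_intercept_se = se_a0,
                           egger_intercept_p = p_a0,
                           sigma = max(1, sigma)))
}

# Weighted median of ratios by linear interpolation of the cumulative weight
# function at 1/2; shared by the estimator and its brute-force test oracle.
weighted_median_point <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- weight[ord] / sum(weight)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(r[1])
  k <- length(r)
  if (0.5 >= s[k]) return(r[k])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

boot_draws <- function(h, n_boot) {
  k <- nrow(h)
  list(g = matrix(stats::rnorm(n_boot * k, mean = rep(h$exposure_beta, each = n_boot),
                               sd = rep(h$exposure_se, each = n_boot)),
                  nrow = n_boot),
       G = matrix(stats::rnorm(n_boot * k, mean = rep(h$outcome_beta, each = n_boot),
                               sd = rep(h$outcome_se, each = n_boot)),
                  nrow = n_boot))
}

#' Weighted median estimate
#'
#' Consistent when instruments carrying at least half the weight are valid.
#' Wald ratios are ordered and the estimate interpolates the ratio at
#' cumulative normalized inverse-variance weight 1/2 (ratio variance taken as
#' `outcome_se^2 / exposure_beta^2`). The standard error comes from a seeded
#' parametric bootstrap resampling both effect sides from their normals.
#'
#' @param h a [harmonized_set()] with at least three variants.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return An [mr_estimate()].
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 1L) {
  k <- nrow(h)
  if (k < 3) estimation_error("weighted median needs at least 3 instruments")
  wc <- wald_components(h)
  beta <- weighted_median_point(wc$ratio, wc$weight)
  boots <- with_seed(seed, {
    d <- boot_draws(h, n_boot)
    vapply(seq_len(n_boot), function(i) {
      g <- d$g[i, ]
      g[g == 0] <- .Machine$double.eps
      weighted_median_point(d$G[i, ] / g, g^2 / h$outcome_se^2)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  mr_estimate("weighted_median", beta, se, z_to_p(beta / se), k)
}

# Mode of the weighted kernel-smoothed ratio density. Bandwidth is
# bandwidth_factor times the modified-Silverman scale
# 0.9 * min(sd, mad) * k^(-1/5) computed on the ratios.
mode_point <- function(ratio, weight, bandwidth_factor) {
  scales <- c(stats::sd(ratio), stats::mad(ratio))
  scales <- scales[is.finite(scales) & scales > 0]
  if (length(scales) == 0) return(ratio[1])  # degenerate: all ratios equal
  bw <- bandwidth_factor * 0.9 * min(scales) * length(ratio)^(-1 / 5)
  # near-duplicate ratios trigger a harmless collapsing warning in density()
  d <- suppressWarnings(stats::density(ratio, weights = weight / sum(weight),
                                       bw = bw, n = 2048))
  d$x[which.max(d$y)]
}

#' Mode-based estimate (weighted or simple)
#'
#' The mode of the kernel-smoothed empirical density of Wald ratios
#' (Gaussian kernel; bandwidth = `bandwidth_factor` times a
#' modified-Silverman scale of the ratios). Weights are normalized inverse
#' variances when `weighted`, uniform otherwise (the "simple mode").
#' Standard error by seeded parametric bootstrap; normal p-value.
#'
#' @param h a [harmonized_set()] with at least three variants.
#' @param weighted use inverse-variance weights (default `TRUE`).
#' @param bandwidth_factor multiplier on the modified-Silverman bandwidth.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return An [mr_estimate()].
#' @export
mr_mode <- function(h, weighted = TRUE, bandwidth_factor = 1,
                    n_boot = 1000, seed = 1L) {
  k <- nrow(h)
  if (k < 3) estimation_error("mode estimator needs at least 3 instruments")
  wc <- wald_components(h)
  wts <- if (weighted) wc$weight else rep(1, k)
  beta <- mode_point(wc$ratio, wts, bandwidth_factor)
  boots <- with_seed(seed, {
    d <- boot_draws(h, n_boot)
    vapply(seq_len(n_boot), function(i) {
      g <- d$g[i, ]
      g[g == 0] <- .Machine$double.eps
      r <- d$G[i, ] / g
      w <- if (weighted) g^2 / h$outcome_se^2 else rep(1, k)
      mode_point(r, w, bandwidth_factor)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  mr_estimate(if (weighted) "weighted_mode" else "simple_mode",
              beta, se, z_to_p(beta / se), k)
}

#' Run the five-estimator battery on a harmonized set
#'
#' IVW (primary), MR-Egger, weighted median, weighted mode, and simple mode;
#' falls back to the Wald ratio when only one instrument is available, and
#' omits estimators whose minimum instrument count is not met.
#'
#' @param h a [harmonized_set()].
#' @param config a [mr_config()] (bootstrap size and seed).
#' @return Named list of [mr_estimate()] objects.
#' @export
mr_all_methods <- function(h, config = mr_config()) {
  k <- nrow(h)
  if (k == 1) return(list(wald = wald_ratio(h)))
  out <- list(ivw = mr_ivw(h))
  if (k >= 3) {
    out$egger <- mr_egger(h)
    out$weighted_median <- mr_weighted_median(h, config$n_boot, config$seed)
    out$weighted_mode <- mr_mode(h, TRUE, 1, config$n_boot, config$seed)
    out$simple_mode <- mr_mode(h, FALSE, 1, config$n_boot, config$seed)
  }
  out
}

#' Tidy a list of MR estimates into a data frame
#'
#' @param estimates list of [mr_estimate()] objects.
#' @param exposure,outcome identifiers recycled into the table.
#' @return Data frame, one row per estimate.
#' @export
tidy_estimates <- function(estimates, exposure = NA_character_,
                           outcome = NA_character_) {
  rows <- lapply(estimates, as.data.frame)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  cbind(data.frame(exposure = exposure, outcome = outcome,
                   stringsAsFactors = FALSE), out)
}
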