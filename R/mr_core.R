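# Closed-form two-sample MR estimators and heterogeneity statistics.
#
# Conventions: normal (z) quantiles for all CIs and p-values; random-effects
# IVW uses multiplicative overdispersion floored at 1 (never tighter than the
# fixed-effect SE); Egger orients instruments so that gamma_j >= 0 before
# fitting.

Z975 <- stats::qnorm(0.975)

#' Construct an MR estimate
#'
#' @param method estimator label (`wald`, `ivw_fixed`, `ivw_random`,
#'   `egger_slope`).
#' @param beta causal effect estimate.
#' @param se standard error (> 0, or 0 for degenerate exact fits).
#' @param n_snp number of instruments used.
#' @param conf_level confidence level (default 0.95).
#' @return An `mr_estimate` list with `beta`, `se`, `ci_low`, `ci_high`,
#'   `pval`, `n_snp`.
#' @export
mr_estimate <- function(method, beta, se, n_snp, conf_level = 0.95) {
  stopifnot(is.finite(beta), is.finite(se), se >= 0, n_snp >= 1)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  pval <- if (beta == 0) 1
          else if (se > 0) max(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
          else .Machine$double.xmin
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - z * se, ci_high = beta + z * se,
                 pval = pval, n_snp = as.integer(n_snp)),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4g [95%% CI %.4g, %.4g], se = %.4g, p = %.3g (%d SNPs)\n",
              x$method, x$beta, x$ci_low, x$ci_high, x$se, x$pval, x$n_snp))
  invisible(x)
}

.het_stats <- function(Q, df) {
  pval <- if (df > 0) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_
  structure(list(Q = Q, df = as.integer(df), pval = pval),
            class = "heterogeneity_stats")
}

#' Wald ratio for a single instrument
#'
#' `beta = Gamma / gamma`, `se = se_Gamma / |gamma|` (first-order, no
#' exposure-side measurement error).
#'
#' @param gamma,se_gamma SNP-exposure effect and SE.
#' @param Gamma,se_Gamma SNP-outcome effect and SE.
#' @return An [mr_estimate] with method `"wald"`.
#' @export
wald_ratio <- function(gamma, se_gamma, Gamma, se_Gamma) {
  stopifnot(se_gamma > 0, se_Gamma > 0)
  if (gamma == 0) stop("undefined ratio: gamma is zero")
  mr_estimate("wald", Gamma / gamma, se_Gamma / abs(gamma), n_snp = 1L)
}

.check_h <- function(h) {
  stopifnot(is.data.frame(h),
            all(c("gamma", "se_gamma", "Gamma", "se_Gamma") %in% names(h)),
            all(h$se_gamma > 0), all(h$se_Gamma > 0))
}

#' Inverse-variance-weighted estimator
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights `1/se_Gamma^2`:
#' `beta = sum(w g G) / sum(w g^2)`, fixed-effect
#' `se = 1/sqrt(sum(w g^2))`. Cochran's Q is the weighted residual sum of
#' squares on `n_snp - 1` degrees of freedom; `mode = "random"` inflates
#' the SE by `max(1, sqrt(Q/df))`. A single instrument delegates to the
#' Wald ratio.
#'
#' @param h a `harmonized_set` (or data.frame with the effect columns).
#' @param mode `"random"` (default) or `"fixed"`.
#' @return List with `estimate` ([mr_estimate]) and `heterogeneity`
#'   (`Q`, `df`, `pval`).
#' @export
mr_ivw <- function(h, mode = c("random", "fixed")) {
  mode <- match.arg(mode)
  .check_h(h)
  J <- nrow(h)
  if (J < 1) stop("empty instrument set")
  if (all(h$gamma == 0)) stop("all SNP-exposure effects are zero")
  if (J == 1L) {
    est <- wald_ratio(h$gamma, h$se_gamma, h$Gamma, h$se_Gamma)
    return(list(estimate = est, heterogeneity = .het_stats(0, 0L)))
  }
  w <- 1 / h$se_Gamma^2
  swg2 <- sum(w * h$gamma^2)
  beta <- sum(w * h$gamma * h$Gamma) / swg2
  se_fixed <- 1 / sqrt(swg2)
  Q <- sum(w * (h$Gamma - beta * h$gamma)^2)
  df <- J - 1L
  se <- if (mode == "random") se_fixed * max(1, sqrt(Q / df)) else se_fixed
  method <- if (mode == "random") "ivw_random" else "ivw_fixed"
  list(estimate = mr_estimate(method, beta, se, J),
       heterogeneity = .het_stats(Q, df))
}

#' MR-Egger regression
#'
#' Weighted least squares `Gamma = b0 + b1 * gamma` with weights
#' `1/se_Gamma^2`, after orienting every instrument so the SNP-exposure
#' effect is non-negative (negate both effects where `gamma < 0`). A
#' non-zero intercept `b0` indicates directional horizontal pleiotropy.
#' Coefficient SEs are inflated by `max(1, sqrt(Q_egger/df))`,
#' `df = n_snp - 2`; CIs and p-values use normal quantiles.
#'
#' @param h a `harmonized_set` with at least 3 instruments.
#' @return List with `slope` ([mr_estimate]), `intercept`,
#'   `intercept_se`, `intercept_pval`, and `heterogeneity`.
#' @export
mr_egger <- function(h) {
  .check_h(h)
  J <- nrow(h)
  if (J < 3L) stop("insufficient instruments for Egger (need >= 3)")
  s <- ifelse(h$gamma < 0, -1, 1)
  g <- s * h$gamma
  G <- s * h$Gamma
  w <- 1 / h$se_Gamma^2
  # normal equations for weighted simple regression
  sw <- sum(w); swx <- sum(w * g); swx2 <- sum(w * g^2)
  swy <- sum(w * G); swxy <- sum(w * g * G)
  det <- sw * swx2 - swx^2
  if (det <= 0) stop("degenerate design: exposure effects have no spread")
  b1 <- (sw * swxy - swx * swy) / det
  b0 <- (swx2 * swy - swx * swxy) / det
  resid <- G - b0 - b1 * g
  Q <- sum(w * resid^2)
  df <- J - 2L
  infl <- max(1, sqrt(Q / df))
  se_b1 <- sqrt(sw / det) * infl
  se_b0 <- sqrt(swx2 / det) * infl
  intercept_pval <- if (b0 == 0) 1
                    else if (se_b0 > 0) max(2 * stats::pnorm(-abs(b0 / se_b0)), .Machine$double.xmin)
                    else .Machine$double.xmin
  list(slope = mr_estimate("egger_slope", b1, se_b1, J),
       intercept = b0, intercept_se = se_b0, intercept_pval = intercept_pval,
       heterogeneity = .het_stats(Q, df))
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_j (Gamma_j - intercept - beta * gamma_j)^2)` with
#' `w_j = 1/se_Gamma_j^2`; degrees of freedom `n_snp - 1` for the IVW
#' model and `n_snp - 2` for Egger; upper-tail chi-square p-value. For the
#' Egger model the instruments are oriented to `gamma >= 0` first, as in
#' [mr_egger].
#'
#' @param h a `harmonized_set`.
#' @param beta slope at which residuals are evaluated.
#' @param model `"ivw"` or `"egger"`.
#' @param intercept intercept term (default 0; used by the Egger model).
#' @return `heterogeneity_stats` list (`Q`, `df`, `pval`).
#' @export
cochran_q <- function(h, beta, model = c("ivw", "egger"), intercept = 0) {
  model <- match.arg(model)
  .check_h(h)
  J <- nrow(h)
  df <- J - if (model == "ivw") 1L else 2L
  if (df <= 0) stop("non-positive degrees of freedom for Cochran's Q")
  if (model == "egger") {
    s <- ifelse(h$gamma < 0, -1, 1)
    g <- s * h$gamma; G <- s * h$Gamma
  } else {
    g <- h$gamma; G <- h$Gamma
  }
  w <- 1 / h$se_Gamma^2
  Q <- sum(w * (G - intercept - beta * g)^2)
  .het_stats(Q, df)
}

#' Leave-one-out IVW estimates
#'
#' Re-fits the IVW estimator excluding each instrument in turn — the
#' standard single-SNP sensitivity display, and the residual basis of the
#' MR-PRESSO test.
#'
#' @param h a `harmonized_set` with at least 3 instruments.
#' @param mode IVW mode, as [mr_ivw].
#' @return data.frame with `variant_id`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `pval`.
#' @export
leave_one_out <- function(h, mode = c("random", "fixed")) {
  mode <- match.arg(mode)
  .check_h(h)
  J <- nrow(h)
  if (J < 3L) stop("need at least 3 instruments for leave-one-out")
  rows <- lapply(seq_len(J), function(j) {
    fit <- mr_ivw(h[-j, , drop = FALSE], mode = mode)$estimate
    data.frame(variant_id = h$variant_id[j], beta = fit$beta, se = fit$se,
               ci_low = fit$ci_low, ci_high = fit$ci_high, pval = fit$pval,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Fixed-effect leave-one-out IVW slopes, vectorized (used by MR-PRESSO).
.loo_slopes_fixed <- function(gamma, Gamma, w) {
  S1 <- sum(w * gamma * Gamma)
  S2 <- sum(w * gamma^2)
  (S1 - w * gamma * Gamma) / (S2 - w * gamma^2)
}

#' Export MR estimates as a results table
#'
#' One row per method with effect, CI, p, and heterogeneity/pleiotropy
#' columns — suitable for forest-plot tooling.
#'
#' @param h the `harmonized_set` analysed.
#' @param ivw_fixed,ivw_random,egger optional fitted results from
#'   [mr_ivw] / [mr_egger]; fitted on the fly when `NULL`.
#' @return data.frame with columns `method`, `exposure`, `outcome`,
#'   `n_snp`, `beta`, `se`, `ci_low`, `ci_high`, `pval`, `Q`, `Q_df`,
#'   `Q_pval`, `egger_intercept`, `egger_intercept_pval`.
#' @export
mr_results_table <- function(h, ivw_fixed = NULL, ivw_random = NULL, egger = NULL) {
  if (is.null(ivw_fixed)) ivw_fixed <- mr_ivw(h, "fixed")
  if (is.null(ivw_random)) ivw_random <- mr_ivw(h, "random")
  if (is.null(egger) && nrow(h) >= 3) egger <- mr_egger(h)
  exposure <- attr(h, "exposure_label") %||% "exposure"
  outcome <- attr(h, "outcome_label") %||% "outcome"
  row_of <- function(est, het, intercept = NA_real_, intercept_p = NA_real_) {
    data.frame(method = est$method, exposure = exposure, outcome = outcome,
               n_snp = est$n_snp, beta = est$beta, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high, pval = est$pval,
               Q = het$Q, Q_df = het$df, Q_pval = het$pval,
               egger_intercept = intercept, egger_intercept_pval = intercept_p,
               stringsAsFactors = FALSE)
  }
  out <- rbind(row_of(ivw_fixed$estimate, ivw_fixed$heterogeneity),
               row_of(ivw_random$estimate, ivw_random$heterogeneity))
  if (!is.null(egger)) {
    out <- rbind(out, row_of(egger$slope, egger$heterogeneity,
                             egger$intercept, egger$intercept_pval))
  }
  out
}
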