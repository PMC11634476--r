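# Resampling-based pleiotropy test in the MR-PRESSO style: a global
# heterogeneity test on the leave-one-out weighted residual sum of squares,
# per-instrument outlier localization, and a distortion test comparing the
# raw and outlier-corrected IVW estimates.
#
# The parametric bootstrap draws, for each of K replicates, SNP-exposure
# effects around the observed gamma_j and SNP-outcome effects around the
# leave-one-out IVW prediction, then recomputes the same weighted LOO RSS.
# Draws are generated instrument-major (all K draws for instrument 1, then
# instrument 2, ...) so results are reproducible for a given seed.

#' MR-PRESSO configuration
#'
#' @param n_sim number of parametric-bootstrap draws K (default 2000,
#'   minimum 100).
#' @param outlier_alpha familywise level for the per-SNP outlier test;
#'   Bonferroni-adjusted across instruments (default 0.05).
#' @param n_boot_distortion bootstrap draws for the distortion null
#'   (default 1000).
#' @param seed RNG seed; the global/outlier stage seeds the stream at
#'   `seed`, the distortion stage continues it.
#' @return A `presso_config` list.
#' @export
presso_config <- function(n_sim = 2000, outlier_alpha = 0.05,
                          n_boot_distortion = 1000, seed = 1L) {
  stopifnot(n_sim >= 100, outlier_alpha > 0, outlier_alpha < 1,
            n_boot_distortion >= 1)
  structure(list(n_sim = as.integer(n_sim), outlier_alpha = outlier_alpha,
                 n_boot_distortion = as.integer(n_boot_distortion),
                 seed = as.integer(seed)),
            class = "presso_config")
}

# observed weighted LOO residuals r_j = w_j (Gamma_j - beta_{-j} gamma_j)^2
.presso_resid_obs <- function(h) {
  w <- 1 / h$se_Gamma^2
  b_loo <- .loo_slopes_fixed(h$gamma, h$Gamma, w)
  w * (h$Gamma - b_loo * h$gamma)^2
}

#' MR-PRESSO global test
#'
#' Observed statistic: `rss_obs = sum_j w_j (Gamma_j - beta_{-j} gamma_j)^2`
#' where `beta_{-j}` is the fixed-effect IVW slope excluding instrument j
#' and `w_j = 1/se_Gamma_j^2`. The null distribution is a parametric
#' bootstrap: `gamma*_j ~ N(gamma_j, se_gamma_j^2)`,
#' `Gamma*_j ~ N(beta_{-j} gamma_j, se_Gamma_j^2)`, with the same LOO RSS
#' recomputed on each simulated set. The Monte-Carlo p-value is
#' `(1 + #\{RSS* >= rss_obs\}) / (K + 1)` and is therefore never below
#' `1/(K+1)`.
#'
#' @param h a `harmonized_set` with at least 4 instruments.
#' @param cfg a [presso_config].
#' @return List with `rss_obs`, `global_pval`, `rss_sim` (length-K
#'   vector), `resid_obs` and `resid_sim` (J x K matrix) for the outlier
#'   stage, and the `cfg` used.
#' @export
presso_global <- function(h, cfg = presso_config()) {
  .check_h(h)
  J <- nrow(h)
  if (J < 4L) stop("too few instruments for MR-PRESSO (need >= 4)")
  K <- cfg$n_sim
  set.seed(cfg$seed)
  w <- 1 / h$se_Gamma^2
  b_loo <- .loo_slopes_fixed(h$gamma, h$Gamma, w)
  resid_obs <- w * (h$Gamma - b_loo * h$gamma)^2
  rss_obs <- sum(resid_obs)

  # instrument-major draws: J x K matrices, one row of K draws per SNP
  gamma_star <- matrix(0, J, K)
  Gamma_star <- matrix(0, J, K)
  for (j in seq_len(J)) {
    gamma_star[j, ] <- stats::rnorm(K, h$gamma[j], h$se_gamma[j])
  }
  for (j in seq_len(J)) {
    Gamma_star[j, ] <- stats::rnorm(K, b_loo[j] * h$gamma[j], h$se_Gamma[j])
  }

  # vectorized LOO slopes per draw: column sums minus own contribution
  wg2 <- gamma_star^2 * w
  wgG <- gamma_star * Gamma_star * w
  S2 <- rep(colSums(wg2), each = J)
  S1 <- rep(colSums(wgG), each = J)
  b_loo_star <- (S1 - wgG) / (S2 - wg2)
  resid_sim <- w * (Gamma_star - b_loo_star * gamma_star)^2
  rss_sim <- colSums(resid_sim)
  global_pval <- (1 + sum(rss_sim >= rss_obs)) / (K + 1)

  list(rss_obs = rss_obs, global_pval = global_pval, rss_sim = rss_sim,
       resid_obs = resid_obs, resid_sim = resid_sim, cfg = cfg)
}

#' MR-PRESSO per-instrument outlier test
#'
#' Each instrument's observed weighted LOO residual is compared with its
#' own bootstrap residuals from [presso_global]:
#' `p_j = (1 + #\{r*_jk >= r_j\}) / (K + 1)`. Instruments with
#' `p_j < outlier_alpha / n_snp` (Bonferroni) are flagged as outliers.
#'
#' @param h the same `harmonized_set` passed to [presso_global].
#' @param global result of [presso_global] on `h`.
#' @return List with `per_snp_pval` (named) and `outliers` (variant ids).
#' @export
presso_outliers <- function(h, global) {
  if (length(global$resid_obs) != nrow(h)) {
    stop("global result does not match the harmonized set")
  }
  K <- global$cfg$n_sim
  per_snp <- (1 + rowSums(global$resid_sim >= global$resid_obs)) / (K + 1)
  names(per_snp) <- h$variant_id
  thr <- global$cfg$outlier_alpha / nrow(h)
  list(per_snp_pval = per_snp,
       outliers = h$variant_id[per_snp < thr])
}

#' MR-PRESSO distortion test
#'
#' Compares the raw IVW estimate with the outlier-corrected one
#' (IVW on the non-outlier instruments) as a percentage distortion
#' `100 (beta_raw - beta_corrected) / |beta_corrected|`. The null
#' distribution removes random same-size subsets (drawn with replacement)
#' of the non-outlier instruments; the p-value is the proportion of
#' absolute null distortions at least as large as the observed one.
#'
#' @param h a `harmonized_set`.
#' @param outliers character vector of outlier variant ids (non-empty).
#' @param cfg a [presso_config].
#' @param mode IVW mode for raw/corrected estimates (default `"random"`).
#' @return List with `beta_raw`, `beta_corrected` ([mr_estimate]s),
#'   `distortion_pct`, `distortion_pval`.
#' @export
presso_distortion <- function(h, outliers, cfg = presso_config(),
                              mode = c("random", "fixed")) {
  mode <- match.arg(mode)
  .check_h(h)
  if (length(outliers) == 0L) stop("distortion test requires a non-empty outlier set")
  clean_ids <- setdiff(h$variant_id, outliers)
  if (length(clean_ids) < 2L) stop("outlier removal leaves fewer than 2 instruments")
  beta_raw <- mr_ivw(h, mode)$estimate
  h_clean <- h[h$variant_id %in% clean_ids, , drop = FALSE]
  beta_corrected <- mr_ivw(h_clean, mode)$estimate
  distortion_pct <- 100 * (beta_raw$beta - beta_corrected$beta) / abs(beta_corrected$beta)

  n_out <- length(outliers)
  b_all <- beta_corrected$beta
  D_null <- numeric(cfg$n_boot_distortion)
  for (b in seq_len(cfg$n_boot_distortion)) {
    drop_ids <- unique(sample(clean_ids, n_out, replace = TRUE))
    keep <- setdiff(clean_ids, drop_ids)
    if (length(keep) < 2L) { D_null[b] <- NA_real_; next }
    b_sub <- mr_ivw(h[h$variant_id %in% keep, , drop = FALSE], mode)$estimate$beta
    D_null[b] <- 100 * (b_all - b_sub) / abs(b_sub)
  }
  D_null <- D_null[!is.na(D_null)]
  distortion_pval <- mean(abs(D_null) >= abs(distortion_pct))
  list(beta_raw = beta_raw, beta_corrected = beta_corrected,
       distortion_pct = distortion_pct, distortion_pval = distortion_pval)
}

#' Run the full MR-PRESSO procedure
#'
#' Orchestrates the global test, the per-instrument outlier test, and —
#' when outliers are found — the distortion test. The outlier-corrected
#' IVW estimate is the one used downstream when pleiotropic instruments
#' are detected.
#'
#' @param h a `harmonized_set` with at least 4 instruments.
#' @param cfg a [presso_config].
#' @param mode IVW mode for the raw/corrected estimates.
#' @return A `presso_result` list: `rss_obs`, `global_pval`,
#'   `per_snp_pval`, `outliers`, `beta_raw`, and (when outliers were
#'   found) `beta_corrected`, `distortion_pct`, `distortion_pval`.
#' @export
mr_presso <- function(h, cfg = presso_config(), mode = c("random", "fixed")) {
  mode <- match.arg(mode)
  glob <- presso_global(h, cfg)
  out <- presso_outliers(h, glob)
  res <- list(rss_obs = glob$rss_obs, global_pval = glob$global_pval,
              per_snp_pval = out$per_snp_pval, outliers = out$outliers,
              beta_raw = mr_ivw(h, mode)$estimate,
              beta_corrected = NULL, distortion_pct = NULL,
              distortion_pval = NULL, cfg = cfg)
  if (length(out$outliers) > 0L &&
      nrow(h) - length(out$outliers) >= 2L) {
    dist <- presso_distortion(h, out$outliers, cfg, mode)
    res$beta_corrected <- dist$beta_corrected
    res$distortion_pct <- dist$distortion_pct
    res$distortion_pval <- dist$distortion_pval
  }
  structure(res, class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("<MR-PRESSO> global p = %.4g (RSS = %.4g), %d outlier(s)\n",
              x$global_pval, x$rss_obs, length(x$outliers)))
  if (length(x$outliers)) {
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
    if (!is.null(x$distortion_pct)) {
      cat(sprintf("  distortion: %.2f%% (p = %.3g); corrected beta = %.4g\n",
                  x$distortion_pct, x$distortion_pval, x$beta_corrected$beta))
    }
  }
  invisible(x)
}

#' Per-instrument MR-PRESSO report table
#'
#' @param h the analysed `harmonized_set`.
#' @param result a `presso_result` from [mr_presso].
#' @return data.frame with one row per instrument: observed weighted LOO
#'   residual, per-SNP p-value, outlier flag.
#' @export
presso_report <- function(h, result) {
  data.frame(variant_id = h$variant_id,
             resid_obs = .presso_resid_obs(h),
             per_snp_pval = unname(result$per_snp_pval[h$variant_id]),
             outlier = h$variant_id %in% result$outliers,
             stringsAsFactors = FALSE)
}
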