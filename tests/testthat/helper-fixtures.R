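# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# A small, fully valid summary-statistics table.
make_sumstats <- function(n = 5, seed = 1, trait = "trait", n_gwas = 50000) {
  set.seed(seed)
  pairs <- matrix(c("A", "G", "T", "C", "G", "A", "C", "T"), ncol = 2, byrow = TRUE)
  pick <- sample.int(nrow(pairs), n, replace = TRUE)
  f <- runif(n, 0.1, 0.45)
  se <- 1 / sqrt(2 * f * (1 - f) * n_gwas)
  beta <- rnorm(n, 0, 0.05)
  sumstats(data.frame(
    variant_id = sprintf("rs%04d", seq_len(n)),
    chrom = as.character(rep_len(1:3, n)),
    pos = seq_len(n) * 50000L,
    effect_allele = pairs[pick, 1],
    other_allele = pairs[pick, 2],
    eaf = f, beta = beta, se = se,
    pval = 2 * pnorm(-abs(beta / se)),
    n = n_gwas, stringsAsFactors = FALSE
  ), trait_label = trait)
}

# Random harmonized set drawn around a true causal slope.
make_hset <- function(J = 10, beta_true = 0.3, seed = 1,
                      se_gamma = 0.02, se_Gamma = 0.03, het_sd = 0) {
  set.seed(seed)
  gamma_t <- rnorm(J, 0, 0.3)
  gamma <- gamma_t + rnorm(J, 0, se_gamma)
  Gamma <- beta_true * gamma_t + rnorm(J, 0, se_Gamma) + rnorm(J, 0, het_sd)
  harmonized_set(gamma, rep(se_gamma, J), Gamma, rep(se_Gamma, J))
}

# Independent weighted-regression oracle (QR path via stats::lm), used to
# cross-check the closed-form IVW and Egger fits.
wls_oracle <- function(gamma, Gamma, w, intercept = FALSE) {
  fit <- if (intercept) stats::lm(Gamma ~ gamma, weights = w)
  else stats::lm(Gamma ~ 0 + gamma, weights = w)
  unname(coef(fit))
}

# Coherent multi-candidate screen fixture: one exposure, one outcome, and
# n_true + n_null candidate mediators sharing the exposure's instruments.
# True candidates have alpha = -0.2, theta = 0.3; nulls have both zero.
make_screen_sim <- function(n_true = 4, n_null = 8, n_gwas = 200000,
                            J_exp = 30, J_med = 20, seed = 1) {
  set.seed(seed)
  alpha_t <- -0.2; theta_t <- 0.3
  total <- -0.29
  delta <- total - n_true * alpha_t * theta_t
  n_cand <- n_true + n_null
  J <- J_exp + n_cand * J_med
  ids <- sprintf("rs%05d", seq_len(J))
  exp_ids <- ids[seq_len(J_exp)]
  f <- runif(J, 0.1, 0.45)
  se <- function(nn) 1 / sqrt(2 * f * (1 - f) * nn)
  gamma_x <- c(rnorm(J_exp, 0, 0.05), rep(0, J - J_exp))

  mk <- function(truth, label) {
    s <- se(n_gwas)
    beta <- truth + rnorm(J, 0, s)
    sumstats(data.frame(variant_id = ids, chrom = "1",
                        pos = seq_len(J) * 1000000L,
                        effect_allele = "A", other_allele = "G",
                        eaf = f, beta = beta, se = s,
                        pval = pmax(2 * pnorm(-abs(beta / s)), 1e-300),
                        n = n_gwas), trait_label = label, quiet = TRUE)
  }

  outcome_truth <- (delta + n_true * alpha_t * theta_t) * gamma_x
  candidates <- list()
  for (c_i in seq_len(n_cand)) {
    is_true <- c_i <= n_true
    own <- J_exp + (c_i - 1) * J_med + seq_len(J_med)
    gamma_mc <- rep(0, J); gamma_mc[own] <- rnorm(J_med, 0, 0.05)
    alpha_c <- if (is_true) alpha_t else 0
    theta_c <- if (is_true) theta_t else 0
    med_truth <- alpha_c * gamma_x + gamma_mc
    outcome_truth <- outcome_truth + theta_c * gamma_mc
    candidates[[paste0(if (is_true) "true" else "null", c_i)]] <-
      list(truth = med_truth, instruments = ids[own])
  }
  for (nm in names(candidates)) {
    candidates[[nm]]$sumstats <- mk(candidates[[nm]]$truth, nm)
    candidates[[nm]]$truth <- NULL
  }
  list(exposure = mk(gamma_x, "exposure"),
       outcome = mk(outcome_truth, "outcome"),
       candidates = candidates, exp_ids = exp_ids,
       true_labels = names(candidates)[seq_len(n_true)],
       null_labels = names(candidates)[n_true + seq_len(n_null)],
       true_proportion = alpha_t * theta_t / total)
}

# Independent brute-force greedy clumping oracle on explicit vectors.
clump_oracle <- function(ids, chrom, pos, pval, r2, r2_max, window_kb) {
  ord <- order(pval, ids)
  remaining <- ids[ord]
  chrom <- chrom[ord]; pos <- pos[ord]
  names(chrom) <- names(pos) <- remaining
  kept <- character(0)
  while (length(remaining) > 0) {
    idx <- remaining[1]
    kept <- c(kept, idx)
    remaining <- remaining[-1]
    if (length(remaining) == 0) break
    drop <- vapply(remaining, function(v) {
      chrom[idx] == chrom[v] &&
        abs(pos[idx] - pos[v]) <= window_kb * 1000 &&
        r2[idx, v] > r2_max
    }, logical(1))
    remaining <- remaining[!drop]
  }
  kept
}
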