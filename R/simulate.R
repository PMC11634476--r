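# Synthetic GWAS summary statistics for an exposure -> mediator -> outcome
# causal chain, with configurable horizontal pleiotropy, LD blocks and
# allele-coding noise. Summary statistics are simulated directly (no
# individual-level genotypes): per-variant sampling standard errors follow
# the standardized-trait approximation se = 1/sqrt(2 f (1-f) n).

#' Simulation configuration for the causal chain generator
#'
#' Defaults mirror a biobank-scale drug-target mediation design: 30
#' exposure instruments and 30 mediator instruments, 200 000 samples per
#' trait GWAS, and a causal chain with exposure->mediator effect
#' `alpha = -0.207`, mediator->outcome effect `theta = 0.274` and direct
#' effect `delta = -0.233282`, so the true total effect is
#' `delta + alpha * theta = -0.290` and the true mediation proportion is
#' about 19.6%.
#'
#' @param n_snp exposure instruments.
#' @param n_snp_med mediator instruments.
#' @param maf_range minor/effect allele frequency range (in (0, 0.5]).
#' @param gamma_sd SD of true SNP-exposure effects (standardized-trait
#'   units per allele copy).
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes.
#' @param alpha exposure -> mediator causal effect.
#' @param theta mediator -> outcome causal effect.
#' @param delta direct exposure -> outcome effect.
#' @param pleio_frac fraction of exposure instruments with horizontal
#'   pleiotropy (default 0).
#' @param pleio_mean,pleio_sd pleiotropy offset distribution
#'   (`mean = 0` gives balanced, `mean != 0` directional pleiotropy).
#' @param ld_block_size instruments per LD block (1 = independent).
#' @param ld_r2 within-block pairwise r^2.
#' @param flip_frac,palindrome_frac allele-coding noise fractions for
#'   [perturb_allele_coding].
#' @param seed RNG seed.
#' @return A `sim_config` list; `true_total()` and `true_proportion()`
#'   read the implied truths.
#' @export
sim_config <- function(n_snp = 30, n_snp_med = 30,
                       maf_range = c(0.05, 0.5), gamma_sd = 0.05,
                       n_exposure = 200000, n_mediator = 200000,
                       n_outcome = 200000,
                       alpha = -0.207, theta = 0.274, delta = -0.233282,
                       pleio_frac = 0, pleio_mean = 0, pleio_sd = 0.005,
                       ld_block_size = 1, ld_r2 = 0,
                       flip_frac = 0, palindrome_frac = 0, seed = 1L) {
  check <- function(cond, field) if (!cond) stop("invalid sim_config field: ", field)
  check(n_snp >= 1, "n_snp"); check(n_snp_med >= 0, "n_snp_med")
  check(length(maf_range) == 2 && maf_range[1] > 0 && maf_range[2] <= 0.5 &&
          maf_range[1] <= maf_range[2], "maf_range")
  check(gamma_sd > 0, "gamma_sd")
  check(n_exposure > 0 && n_mediator > 0 && n_outcome > 0, "sample sizes")
  check(pleio_frac >= 0 && pleio_frac < 1, "pleio_frac")
  check(pleio_sd >= 0, "pleio_sd")
  check(ld_block_size >= 1, "ld_block_size")
  check(ld_r2 >= 0 && ld_r2 < 1, "ld_r2")
  check(flip_frac >= 0 && flip_frac < 1, "flip_frac")
  check(palindrome_frac >= 0 && palindrome_frac < 1, "palindrome_frac")
  structure(list(n_snp = as.integer(n_snp), n_snp_med = as.integer(n_snp_med),
                 maf_range = maf_range, gamma_sd = gamma_sd,
                 n_exposure = n_exposure, n_mediator = n_mediator,
                 n_outcome = n_outcome, alpha = alpha, theta = theta,
                 delta = delta, pleio_frac = pleio_frac,
                 pleio_mean = pleio_mean, pleio_sd = pleio_sd,
                 ld_block_size = as.integer(ld_block_size), ld_r2 = ld_r2,
                 flip_frac = flip_frac, palindrome_frac = palindrome_frac,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' True total effect implied by a simulation configuration
#' @param cfg a [sim_config] (or `sim_truth`).
#' @return `delta + alpha * theta`.
#' @export
true_total <- function(cfg) cfg$delta + cfg$alpha * cfg$theta

#' True mediation proportion implied by a simulation configuration
#' @param cfg a [sim_config] (or `sim_truth`).
#' @return `alpha * theta / (delta + alpha * theta)` (NA when the total is 0).
#' @export
true_proportion <- function(cfg) {
  tot <- true_total(cfg)
  if (tot == 0) NA_real_ else cfg$alpha * cfg$theta / tot
}

.nonpalindromic_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                                  "G", "A", "C", "A", "G", "T", "C", "T"),
                                ncol = 2, byrow = TRUE)

.sim_table <- function(ids, chrom, pos, ea, oa, f, truth_beta, n, label) {
  se <- 1 / sqrt(2 * f * (1 - f) * n)
  beta <- truth_beta + stats::rnorm(length(ids), 0, se)
  pval <- 2 * stats::pnorm(-abs(beta / se))
  pval <- pmax(pval, .Machine$double.xmin)
  sumstats(data.frame(variant_id = ids, chrom = chrom, pos = pos,
                      effect_allele = ea, other_allele = oa, eaf = f,
                      beta = beta, se = se, pval = pval, n = n,
                      stringsAsFactors = FALSE),
           trait_label = label, quiet = TRUE)
}

#' Simulate GWAS summary statistics for a causal chain
#'
#' Generates exposure, mediator and outcome summary-statistics tables for
#' `n_snp` exposure instruments and `n_snp_med` mediator instruments under
#' the structural model: mediator = alpha * exposure, outcome =
#' delta * exposure + theta * mediator. True per-SNP effects on the
#' instrumented trait are `N(0, gamma_sd^2)`; a `pleio_frac` subset of
#' exposure instruments receives horizontal-pleiotropy offsets
#' `N(pleio_mean, pleio_sd^2)` added to the SNP-outcome (and SNP-mediator)
#' truth. Observed effects add sampling noise with
#' `se = 1/sqrt(2 f (1-f) n_trait)`; the three traits use independent
#' noise (two-sample designs, no overlap). The LD matrix has blocks of
#' `ld_block_size` adjacent variants sharing pairwise `ld_r2`.
#'
#' @param cfg a [sim_config].
#' @return List with `exposure`, `mediator`, `outcome` ([sumstats]
#'   tables), `ld` ([ld_matrix]) and `truth` (a `sim_truth`: per-SNP true
#'   effects and pleiotropy offsets, the chain parameters, true total
#'   effect and mediation proportion, and instrument role labels).
#' @export
simulate_chain <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  J1 <- cfg$n_snp; J2 <- cfg$n_snp_med; J <- J1 + J2
  ids <- sprintf("rs%05d", seq_len(J))
  role <- rep(c("exposure_iv", "mediator_iv"), c(J1, J2))

  # LD blocks of adjacent variants; blocks 1 Mb apart, members 10 kb apart
  block <- (seq_len(J) - 1) %/% cfg$ld_block_size
  chrom <- as.character(block %% 22L + 1L)
  pos <- 1000000L + (block %/% 22L) * 1000000L +
    ((seq_len(J) - 1) %% cfg$ld_block_size) * 10000L

  pair <- .nonpalindromic_pairs[sample.int(nrow(.nonpalindromic_pairs), J,
                                           replace = TRUE), , drop = FALSE]
  f <- stats::runif(J, cfg$maf_range[1], cfg$maf_range[2])

  gamma_x <- c(stats::rnorm(J1, 0, cfg$gamma_sd), rep(0, J2))
  gamma_m <- c(rep(0, J1), stats::rnorm(J2, 0, cfg$gamma_sd))

  pleio_out <- rep(0, J)
  pleio_med <- rep(0, J)
  n_pleio <- round(cfg$pleio_frac * J1)
  pleio_ids <- character(0)
  if (n_pleio > 0) {
    idx <- sample.int(J1, n_pleio)
    pleio_out[idx] <- stats::rnorm(n_pleio, cfg$pleio_mean, cfg$pleio_sd)
    pleio_med[idx] <- stats::rnorm(n_pleio, cfg$pleio_mean, cfg$pleio_sd)
    pleio_ids <- ids[idx]
  }

  beta_x_true <- gamma_x
  beta_m_true <- cfg$alpha * gamma_x + gamma_m + pleio_med
  beta_y_true <- (cfg$delta + cfg$alpha * cfg$theta) * gamma_x +
    cfg$theta * gamma_m + pleio_out

  exposure <- .sim_table(ids, chrom, pos, pair[, 1], pair[, 2], f,
                         beta_x_true, cfg$n_exposure, "exposure")
  mediator <- .sim_table(ids, chrom, pos, pair[, 1], pair[, 2], f,
                         beta_m_true, cfg$n_mediator, "mediator")
  outcome <- .sim_table(ids, chrom, pos, pair[, 1], pair[, 2], f,
                        beta_y_true, cfg$n_outcome, "outcome")

  r2 <- diag(J)
  if (cfg$ld_r2 > 0 && cfg$ld_block_size > 1) {
    for (b in unique(block)) {
      members <- which(block == b)
      r2[members, members] <- cfg$ld_r2
      diag(r2)[members] <- 1
    }
  }
  ld <- ld_matrix(r2, ids,
                  positions = data.frame(variant_id = ids, chrom = chrom,
                                         pos = pos, stringsAsFactors = FALSE))

  truth <- structure(list(
    snps = data.frame(variant_id = ids, role = role, gamma_x = gamma_x,
                      gamma_m = gamma_m, beta_exposure_true = beta_x_true,
                      beta_mediator_true = beta_m_true,
                      beta_outcome_true = beta_y_true,
                      pleio_outcome = pleio_out, pleio_mediator = pleio_med,
                      stringsAsFactors = FALSE),
    alpha = cfg$alpha, theta = cfg$theta, delta = cfg$delta,
    total = true_total(cfg), proportion = true_proportion(cfg),
    pleiotropic_ids = pleio_ids, outlier_ids = character(0),
    flipped_ids = character(0), palindromic_ids = character(0),
    seed = cfg$seed), class = "sim_truth")

  list(exposure = exposure, mediator = mediator, outcome = outcome,
       ld = ld, truth = truth)
}

#' Perturb allele coding of a summary-statistics table
#'
#' Stress-test input for harmonization: a random `flip_frac` subset of
#' rows has effect/other alleles swapped, beta negated and EAF
#' complemented (an equivalent re-expression of the same association); a
#' random `palindrome_frac` subset has its allele pair rewritten to A/T or
#' C/G. Perturbed ids are recorded in the `flipped_ids` /
#' `palindromic_ids` attributes.
#'
#' @param table a [sumstats] table.
#' @param flip_frac,palindrome_frac fractions in \[0, 1).
#' @param seed RNG seed.
#' @return The perturbed [sumstats] table.
#' @export
perturb_allele_coding <- function(table, flip_frac = 0, palindrome_frac = 0,
                                  seed = 1L) {
  if (flip_frac < 0 || flip_frac >= 1 || palindrome_frac < 0 || palindrome_frac >= 1) {
    stop("flip_frac and palindrome_frac must lie in [0, 1)")
  }
  set.seed(seed)
  out <- table
  n <- nrow(out)
  flip_idx <- sample.int(n, round(flip_frac * n))
  if (length(flip_idx) > 0) {
    ea <- out$effect_allele[flip_idx]
    out$effect_allele[flip_idx] <- out$other_allele[flip_idx]
    out$other_allele[flip_idx] <- ea
    out$beta[flip_idx] <- -out$beta[flip_idx]
    out$eaf[flip_idx] <- 1 - out$eaf[flip_idx]
  }
  pal_idx <- sample.int(n, round(palindrome_frac * n))
  if (length(pal_idx) > 0) {
    pal_pair <- matrix(c("A", "T", "C", "G"), ncol = 2, byrow = TRUE)
    pick <- sample.int(2, length(pal_idx), replace = TRUE)
    out$effect_allele[pal_idx] <- pal_pair[pick, 1]
    out$other_allele[pal_idx] <- pal_pair[pick, 2]
  }
  attr(out, "flipped_ids") <- out$variant_id[flip_idx]
  attr(out, "palindromic_ids") <- out$variant_id[pal_idx]
  out
}

#' Plant pleiotropic outliers in an outcome table
#'
#' Adds `offset_in_se * se_j` to the outcome beta of `k` randomly chosen
#' exposure instruments (and recomputes their p-values), recording the
#' planted ids in the truth object — the ground truth for outlier-test
#' power and recall studies.
#'
#' @param outcome outcome [sumstats] table from [simulate_chain].
#' @param truth the matching `sim_truth`.
#' @param k number of outliers to plant (`k < n_snp`).
#' @param offset_in_se offset size in units of the variant's outcome SE.
#' @param seed RNG seed.
#' @return List with the modified `outcome` table and updated `truth`.
#' @export
plant_outliers <- function(outcome, truth, k, offset_in_se = 8, seed = 1L) {
  exp_ids <- truth$snps$variant_id[truth$snps$role == "exposure_iv"]
  if (k >= length(exp_ids)) stop("k must be smaller than the number of exposure instruments")
  set.seed(seed)
  if (k > 0) {
    chosen <- sample(exp_ids, k)
    idx <- match(chosen, outcome$variant_id)
    outcome$beta[idx] <- outcome$beta[idx] + offset_in_se * outcome$se[idx]
    outcome$pval[idx] <- pmax(2 * stats::pnorm(-abs(outcome$beta[idx] / outcome$se[idx])),
                              .Machine$double.xmin)
    truth$outlier_ids <- sort(chosen)
  }
  list(outcome = outcome, truth = truth)
}
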