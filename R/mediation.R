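# Two-step mediation MR: product-of-coefficients indirect effect,
# delta-method SE, mediation proportion, and the multi-candidate screen.

#' Delta-method mediation effect
#'
#' Combines three MR estimates — exposure->mediator (`b1`),
#' mediator->outcome (`b2`), and the total exposure->outcome effect — into
#' the indirect effect `b1 * b2` and the mediation proportion
#' `b1 * b2 / beta_total`, with a first-order delta-method SE. The two
#' stage estimates come from non-overlapping samples, so their covariance
#' is taken as zero: `se_indirect = sqrt(b2^2 s1^2 + b1^2 s2^2)`.
#'
#' `denominator_mode` controls how the total effect enters the proportion
#' SE: `"fixed"` (default) treats it as known,
#' `se_prop = se_indirect / |beta_total|`; `"propagated"` adds its
#' sampling variance,
#' `se_prop = |prop| sqrt(se_ind^2/ind^2 + s_tot^2/b_tot^2)`.
#'
#' @param beta_xm [mr_estimate] for exposure -> mediator.
#' @param beta_my [mr_estimate] for mediator -> outcome.
#' @param beta_total [mr_estimate] for exposure -> outcome.
#' @param denominator_mode `"fixed"` or `"propagated"`.
#' @param conf_level confidence level (default 0.95).
#' @return A `mediation_result` list: `beta_total`, `beta_xm`, `beta_my`,
#'   `indirect`, `indirect_se`, `proportion`, `proportion_se`,
#'   `proportion_ci_low`, `proportion_ci_high` (proportion on the 0-1
#'   scale; multiply by 100 for percent).
#' @export
mediation_effect <- function(beta_xm, beta_my, beta_total,
                             denominator_mode = c("fixed", "propagated"),
                             conf_level = 0.95) {
  denominator_mode <- match.arg(denominator_mode)
  as_est <- function(x, lab) {
    if (inherits(x, "mr_estimate")) return(x)
    if (is.list(x) && !is.null(x$beta) && !is.null(x$se)) {
      return(mr_estimate(lab, x$beta, x$se, x$n_snp %||% 1L))
    }
    stop("expected an mr_estimate for ", lab)
  }
  beta_xm <- as_est(beta_xm, "xm")
  beta_my <- as_est(beta_my, "my")
  beta_total <- as_est(beta_total, "total")
  if (beta_total$beta == 0) stop("undefined proportion: total effect is zero")

  b1 <- beta_xm$beta; s1 <- beta_xm$se
  b2 <- beta_my$beta; s2 <- beta_my$se
  indirect <- b1 * b2
  indirect_se <- sqrt(b2^2 * s1^2 + b1^2 * s2^2)
  proportion <- indirect / beta_total$beta
  if (denominator_mode == "fixed") {
    proportion_se <- indirect_se / abs(beta_total$beta)
  } else {
    if (indirect == 0) {
      proportion_se <- indirect_se / abs(beta_total$beta)
    } else {
      proportion_se <- abs(proportion) *
        sqrt(indirect_se^2 / indirect^2 + beta_total$se^2 / beta_total$beta^2)
    }
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (proportion < 0 || proportion > 1) {
    warning(sprintf("mediation proportion %.3f lies outside [0, 1]", proportion))
  }
  structure(list(beta_total = beta_total, beta_xm = beta_xm, beta_my = beta_my,
                 indirect = indirect, indirect_se = indirect_se,
                 proportion = proportion, proportion_se = proportion_se,
                 proportion_ci_low = proportion - z * proportion_se,
                 proportion_ci_high = proportion + z * proportion_se,
                 denominator_mode = denominator_mode),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("indirect = %.4g (se %.4g); proportion mediated = %.2f%% [95%% CI %.2f%%, %.2f%%]\n",
              x$indirect, x$indirect_se, 100 * x$proportion,
              100 * x$proportion_ci_low, 100 * x$proportion_ci_high))
  invisible(x)
}

#' Screen configuration for candidate mediators
#'
#' @param alpha_screen per-stage significance level (default 0.05).
#' @param multiplicity adjustment across candidates at the
#'   mediator->outcome stage: `"none"` (default), `"bh_fdr"`, or
#'   `"bonferroni"`.
#' @param require_direction_consistency require
#'   `sign(b1 * b2) == sign(beta_total)` to call a candidate a mediator
#'   (default TRUE).
#' @param estimator IVW mode used throughout (`"random"` or `"fixed"`).
#' @param denominator_mode passed to [mediation_effect].
#' @return A `screen_config` list.
#' @export
screen_config <- function(alpha_screen = 0.05,
                          multiplicity = c("none", "bh_fdr", "bonferroni"),
                          require_direction_consistency = TRUE,
                          estimator = c("random", "fixed"),
                          denominator_mode = c("fixed", "propagated")) {
  multiplicity <- match.arg(multiplicity)
  stopifnot(alpha_screen > 0, alpha_screen < 1)
  structure(list(alpha_screen = alpha_screen, multiplicity = multiplicity,
                 require_direction_consistency = require_direction_consistency,
                 estimator = match.arg(estimator),
                 denominator_mode = match.arg(denominator_mode)),
            class = "screen_config")
}

.subset_instruments <- function(table, instrument_ids, stage) {
  ids <- if (is.data.frame(instrument_ids)) instrument_ids$variant_id else instrument_ids
  out <- table[table$variant_id %in% ids, , drop = FALSE]
  if (nrow(out) == 0L) stop("no instruments available for stage: ", stage)
  out
}

#' Two-step mediation MR
#'
#' Step 1 estimates the exposure -> mediator effect with the exposure's
#' instruments; step 2 estimates the mediator -> outcome effect with the
#' mediator's own instruments; the total exposure -> outcome effect uses
#' the exposure instruments. Mediator instruments that are also exposure
#' instruments are dropped (with a message) so the second step is not
#' contaminated by the exposure's direct pathway. The three estimates are
#' combined by [mediation_effect].
#'
#' @param exposure,mediator,outcome [sumstats] tables containing, at
#'   minimum, the instrument variants for each stage.
#' @param exposure_instruments,mediator_instruments variant id vectors (or
#'   [sumstats] tables whose `variant_id`s are used).
#' @param cfg a [screen_config].
#' @param ... passed to [harmonize_pair] (palindrome policy etc.).
#' @return A `mediation_result`; stage fits are attached as attributes
#'   `fit_xm`, `fit_my`, `fit_total`.
#' @export
two_step_mediation <- function(exposure, mediator, outcome,
                               exposure_instruments, mediator_instruments,
                               cfg = screen_config(), ...) {
  exp_ids <- if (is.data.frame(exposure_instruments)) exposure_instruments$variant_id else exposure_instruments
  med_ids <- if (is.data.frame(mediator_instruments)) mediator_instruments$variant_id else mediator_instruments
  overlap <- intersect(med_ids, exp_ids)
  if (length(overlap) > 0L) {
    message(length(overlap), " mediator instrument(s) overlap the exposure set; dropped")
    med_ids <- setdiff(med_ids, exp_ids)
  }
  if (length(med_ids) == 0L) stop("no instruments available for stage: mediator->outcome")

  h_xm <- harmonize_pair(.subset_instruments(exposure, exp_ids, "exposure->mediator"),
                         mediator, ...)
  h_my <- harmonize_pair(.subset_instruments(mediator, med_ids, "mediator->outcome"),
                         outcome, ...)
  h_tot <- harmonize_pair(.subset_instruments(exposure, exp_ids, "exposure->outcome"),
                          outcome, ...)
  fit_xm <- mr_ivw(h_xm, cfg$estimator)
  fit_my <- mr_ivw(h_my, cfg$estimator)
  fit_tot <- mr_ivw(h_tot, cfg$estimator)
  res <- mediation_effect(fit_xm$estimate, fit_my$estimate, fit_tot$estimate,
                          denominator_mode = cfg$denominator_mode)
  attr(res, "fit_xm") <- fit_xm
  attr(res, "fit_my") <- fit_my
  attr(res, "fit_total") <- fit_tot
  res
}

#' Screen candidate mediators of an exposure-outcome effect
#'
#' Stage A runs mediator -> outcome MR for every candidate (each with its
#' own instruments, exposure instruments excluded) and retains candidates
#' whose association passes `alpha_screen` after the configured
#' multiplicity adjustment. Stage B runs exposure -> mediator MR for the
#' retained candidates at the raw `alpha_screen`. Qualifying candidates —
#' optionally also required to have `sign(b1 b2) == sign(beta_total)` —
#' get a full [mediation_effect]. Candidates with no usable instruments
#' are recorded and skipped with a warning.
#'
#' @param exposure,outcome [sumstats] tables.
#' @param candidates named list; each element a list with `sumstats` (the
#'   candidate's GWAS table) and `instruments` (variant ids or a table).
#' @param exposure_instruments instruments for the exposure.
#' @param cfg a [screen_config].
#' @param ... passed to [harmonize_pair].
#' @return A `screen_table` data.frame, one row per candidate: stage-A and
#'   stage-B effects/SEs/p-values, `qualifies`, and the mediation columns
#'   (`indirect`, `proportion`, `proportion_se`, CI) for qualifiers.
#'   Attributes: `beta_total` (the exposure->outcome [mr_estimate]),
#'   `n_positive`/`n_negative` (direction counts among stage-A hits).
#' @export
screen_mediators <- function(exposure, outcome, candidates,
                             exposure_instruments, cfg = screen_config(), ...) {
  if (length(candidates) == 0L) stop("no candidate mediators supplied")
  if (is.null(names(candidates)) || any(!nzchar(names(candidates)))) {
    stop("candidates must be a named list")
  }
  exp_ids <- if (is.data.frame(exposure_instruments)) exposure_instruments$variant_id else exposure_instruments
  h_tot <- harmonize_pair(.subset_instruments(exposure, exp_ids, "exposure->outcome"),
                          outcome, ...)
  beta_total <- mr_ivw(h_tot, cfg$estimator)$estimate

  labels <- names(candidates)
  n_cand <- length(labels)
  tmpl <- rep(NA_real_, n_cand)
  tab <- data.frame(mediator = labels,
                    n_snp_my = NA_integer_, beta_my = tmpl, se_my = tmpl,
                    p_my = tmpl, p_my_adj = tmpl,
                    n_snp_xm = NA_integer_, beta_xm = tmpl, se_xm = tmpl, p_xm = tmpl,
                    qualifies = FALSE, indirect = tmpl, indirect_se = tmpl,
                    proportion = tmpl, proportion_se = tmpl,
                    proportion_ci_low = tmpl, proportion_ci_high = tmpl,
                    note = "", stringsAsFactors = FALSE)

  stageA <- vector("list", n_cand)
  for (i in seq_len(n_cand)) {
    cand <- candidates[[i]]
    med_ids <- if (is.data.frame(cand$instruments)) cand$instruments$variant_id else cand$instruments
    med_ids <- setdiff(med_ids, exp_ids)
    fitA <- tryCatch({
      if (length(med_ids) == 0L) stop("no instruments after excluding exposure set")
      h_my <- harmonize_pair(.subset_instruments(cand$sumstats, med_ids, "mediator->outcome"),
                             outcome, ...)
      mr_ivw(h_my, cfg$estimator)
    }, error = function(e) e)
    if (inherits(fitA, "error")) {
      warning("candidate '", labels[i], "' skipped: ", conditionMessage(fitA))
      tab$note[i] <- conditionMessage(fitA)
    } else {
      stageA[[i]] <- fitA
      tab$n_snp_my[i] <- fitA$estimate$n_snp
      tab$beta_my[i] <- fitA$estimate$beta
      tab$se_my[i] <- fitA$estimate$se
      tab$p_my[i] <- fitA$estimate$pval
    }
  }

  ok <- !is.na(tab$p_my)
  adj_method <- switch(cfg$multiplicity, none = "none", bh_fdr = "BH",
                       bonferroni = "bonferroni")
  tab$p_my_adj[ok] <- stats::p.adjust(tab$p_my[ok], method = adj_method)
  retained <- ok & tab$p_my_adj < cfg$alpha_screen

  for (i in which(retained)) {
    cand <- candidates[[i]]
    fitB <- tryCatch({
      h_xm <- harmonize_pair(.subset_instruments(exposure, exp_ids, "exposure->mediator"),
                             cand$sumstats, ...)
      mr_ivw(h_xm, cfg$estimator)
    }, error = function(e) e)
    if (inherits(fitB, "error")) {
      warning("candidate '", labels[i], "' stage-B failed: ", conditionMessage(fitB))
      tab$note[i] <- conditionMessage(fitB)
      next
    }
    tab$n_snp_xm[i] <- fitB$estimate$n_snp
    tab$beta_xm[i] <- fitB$estimate$beta
    tab$se_xm[i] <- fitB$estimate$se
    tab$p_xm[i] <- fitB$estimate$pval
    if (fitB$estimate$pval >= cfg$alpha_screen) next
    med <- suppressWarnings(
      mediation_effect(fitB$estimate, stageA[[i]]$estimate, beta_total,
                       denominator_mode = cfg$denominator_mode))
    direction_ok <- !cfg$require_direction_consistency ||
      sign(med$indirect) == sign(beta_total$beta)
    tab$indirect[i] <- med$indirect
    tab$indirect_se[i] <- med$indirect_se
    tab$proportion[i] <- med$proportion
    tab$proportion_se[i] <- med$proportion_se
    tab$proportion_ci_low[i] <- med$proportion_ci_low
    tab$proportion_ci_high[i] <- med$proportion_ci_high
    tab$qualifies[i] <- direction_ok
    if (!direction_ok) tab$note[i] <- "direction-inconsistent"
  }

  structure(tab,
            beta_total = beta_total,
            n_positive = sum(retained & tab$beta_my > 0, na.rm = TRUE),
            n_negative = sum(retained & tab$beta_my < 0, na.rm = TRUE),
            class = c("screen_table", "data.frame"))
}

#' Write a screen table and its volcano companion file
#'
#' The main file holds the full screen in stable column order; the volcano
#' file holds `mediator`, `beta_my`, `neg_log10_p` for plotting.
#'
#' @param tab a `screen_table`.
#' @param path main output path.
#' @param volcano_path companion path (default `<path>.volcano`).
#' @export
write_screen_table <- function(tab, path, volcano_path = paste0(path, ".volcano")) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  volcano <- data.frame(mediator = tab$mediator, beta_my = tab$beta_my,
                        neg_log10_p = -log10(tab$p_my))
  utils::write.table(volcano, volcano_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
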