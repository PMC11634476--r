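# Configuration-driven orchestration of the full analysis: simulate,
# two-sample MR, and mediation/screening runs with a seed echo and
# telescoping per-stage record counts.

.pkg_version <- function() as.character(utils::packageVersion("mrmediate"))

#' Load a pipeline configuration
#'
#' Accepts a YAML file path or an already-parsed list. Recognized keys:
#' `seed`, `out_dir`, `exposure`/`outcome`/`mediator` (each with `path`,
#' optional `trait_label`, `column_map`), `mediators` (list of candidates
#' with `label`, `path`, `instruments_path`), `ld` (`path`,
#' `positions_path`), `estimates_file` (pre-fitted mediation mode),
#' `selection`, `presso`, `screen`, `harmonize`, `sim` blocks mirroring
#' the corresponding config constructors, and `run_presso`.
#'
#' @param config file path or list.
#' @param seed optional seed override.
#' @param out_dir optional output-directory override.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(config, seed = NULL, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config must be a YAML file path or a list")
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$out_dir <- cfg$out_dir %||% "."
  cfg$run_presso <- isTRUE(cfg$run_presso %||% TRUE)
  cfg$selection <- do.call(selection_config, cfg$selection %||% list())
  cfg$presso <- do.call(presso_config,
                        utils::modifyList(list(seed = cfg$seed),
                                          cfg$presso %||% list()))
  cfg$screen <- do.call(screen_config, cfg$screen %||% list())
  cfg$harmonize <- cfg$harmonize %||% list()
  structure(cfg, class = "pipeline_config")
}

.read_trait <- function(spec, what) {
  if (is.null(spec) || is.null(spec$path)) stop("config is missing the '", what, "' input")
  if (!file.exists(spec$path)) stop(what, " file does not exist: ", spec$path)
  read_sumstats(spec$path, column_map = spec$column_map,
                trait_label = spec$trait_label %||% what)
}

.write_report <- function(report, out_dir, name) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, name)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

#' Simulate a synthetic study and write its files
#'
#' Runs [simulate_chain] and writes the exposure/mediator/outcome tables
#' in the canonical dialect, the LD matrix with its positions sidecar, a
#' truth sidecar (JSON) and a config echo with the seed.
#'
#' @param config pipeline config (path or list); the `sim` block holds
#'   [sim_config] fields.
#' @param seed,out_dir overrides.
#' @return Invisibly, the list of written paths.
#' @export
pipeline_simulate <- function(config = list(), seed = NULL, out_dir = NULL) {
  cfg <- pipeline_config(config, seed, out_dir)
  sim_cfg <- do.call(sim_config, utils::modifyList(list(seed = cfg$seed),
                                                   cfg$sim %||% list()))
  sim <- simulate_chain(sim_cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    exposure = file.path(cfg$out_dir, "exposure.tsv"),
    mediator = file.path(cfg$out_dir, "mediator.tsv"),
    outcome = file.path(cfg$out_dir, "outcome.tsv"),
    ld = file.path(cfg$out_dir, "ld.tsv"),
    truth = file.path(cfg$out_dir, "truth.json"),
    config = file.path(cfg$out_dir, "config_echo.json")
  )
  write_sumstats(sim$exposure, paths$exposure)
  write_sumstats(sim$mediator, paths$mediator)
  write_sumstats(sim$outcome, paths$outcome)
  write_ld_matrix(sim$ld, paths$ld)
  jsonlite::write_json(unclass(sim$truth), paths$truth, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  jsonlite::write_json(list(version = .pkg_version(), seed = cfg$seed,
                            sim = unclass(sim_cfg)),
                       paths$config, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

.prepare_instruments <- function(exposure, cfg, ld = NULL) {
  counts <- list(read = nrow(exposure),
                 dropped = attr(exposure, "n_dropped") %||% 0L)
  sel <- select_by_pvalue(exposure, cfg$selection$p_threshold)
  counts$selected <- nrow(sel)
  if (nrow(sel) == 0L) stop("stage select: no variants pass the p-value threshold")
  clumped <- if (!is.null(ld)) {
    clump(sel, ld, cfg$selection$r2_max, cfg$selection$window_kb)
  } else sel
  counts$clumped <- nrow(clumped)
  strong <- filter_weak(clumped, cfg$selection$f_min)
  counts$weak_filtered <- nrow(strong)
  list(instruments = strong, counts = counts,
       strength = f_statistics(clumped, cfg$selection$f_min))
}

#' Run the two-sample MR pipeline
#'
#' select -> clump -> F-filter -> harmonize -> IVW (fixed and random) +
#' MR-Egger + Cochran's Q + leave-one-out + (optionally) MR-PRESSO.
#' Writes `mr_results.tsv`, `leave_one_out.tsv`, `presso_report.tsv` and
#' `mr_report.json` under `out_dir`.
#'
#' @param config pipeline config (path or list) naming `exposure`,
#'   `outcome` and optionally `ld` inputs.
#' @param seed,out_dir overrides.
#' @return The run report (list) with telescoping stage counts, all
#'   estimates, and the MR-PRESSO result.
#' @export
pipeline_mr <- function(config, seed = NULL, out_dir = NULL) {
  cfg <- pipeline_config(config, seed, out_dir)
  exposure <- .read_trait(cfg$exposure, "exposure")
  outcome <- .read_trait(cfg$outcome, "outcome")
  ld <- if (!is.null(cfg$ld$path)) {
    read_ld_matrix(cfg$ld$path,
                   cfg$ld$positions_path %||% paste0(cfg$ld$path, ".positions"))
  }
  prep <- .prepare_instruments(exposure, cfg, ld)
  h <- do.call(harmonize_pair,
               c(list(exposure = prep$instruments, outcome = outcome),
                 cfg$harmonize))
  counts <- prep$counts
  counts$harmonized <- nrow(h)

  ivw_f <- mr_ivw(h, "fixed")
  ivw_r <- mr_ivw(h, "random")
  egger <- if (nrow(h) >= 3) mr_egger(h)
  loo <- if (nrow(h) >= 3) leave_one_out(h)
  presso <- if (cfg$run_presso && nrow(h) >= 4) mr_presso(h, cfg$presso)

  results <- mr_results_table(h, ivw_f, ivw_r, egger)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(results, file.path(cfg$out_dir, "mr_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(loo)) {
    utils::write.table(loo, file.path(cfg$out_dir, "leave_one_out.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(presso)) {
    utils::write.table(presso_report(h, presso),
                       file.path(cfg$out_dir, "presso_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report <- list(version = .pkg_version(), seed = cfg$seed,
                 exposure = attr(exposure, "trait_label"),
                 outcome = attr(outcome, "trait_label"),
                 counts = counts,
                 mean_F = prep$strength$mean_F,
                 results = results,
                 presso = if (!is.null(presso)) {
                   list(global_pval = presso$global_pval,
                        outliers = as.list(presso$outliers),
                        distortion_pct = presso$distortion_pct,
                        distortion_pval = presso$distortion_pval,
                        beta_raw = presso$beta_raw$beta,
                        beta_corrected = if (!is.null(presso$beta_corrected))
                          presso$beta_corrected$beta)
                 },
                 config = list(selection = unclass(cfg$selection),
                               presso = unclass(cfg$presso)))
  .write_report(report, cfg$out_dir, "mr_report.json")
  invisible(report)
}

.read_prefitted <- function(path) {
  est <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("stage", "beta", "se")
  if (!all(need %in% names(est))) {
    stop("pre-fitted estimates file needs columns: ", paste(need, collapse = ", "))
  }
  get <- function(stage) {
    row <- est[est$stage == stage, , drop = FALSE]
    if (nrow(row) != 1L) stop("pre-fitted estimates file needs exactly one '",
                              stage, "' row")
    mr_estimate(stage, row$beta, row$se, row$n_snp %||% 1L)
  }
  list(xm = get("exposure_mediator"), my = get("mediator_outcome"),
       total = get("exposure_outcome"))
}

#' Run the mediation / mediator-screen pipeline
#'
#' Three modes, chosen from the configuration: `estimates_file` (a
#' tab-delimited file with `stage` in \{exposure_mediator,
#' mediator_outcome, exposure_outcome\}, `beta`, `se`) runs the
#' delta-method arithmetic alone; a single `mediator` input runs
#' [two_step_mediation]; a `mediators` list runs [screen_mediators].
#' Writes `mediation.tsv` (and `screen.tsv` with its volcano companion in
#' screen mode) plus `mediation_report.json`.
#'
#' @param config pipeline config (path or list).
#' @param seed,out_dir overrides.
#' @return The run report (list); proportions are reported in percent.
#' @export
pipeline_mediate <- function(config, seed = NULL, out_dir = NULL) {
  cfg <- pipeline_config(config, seed, out_dir)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(version = .pkg_version(), seed = cfg$seed)

  med_row <- function(m) data.frame(
    beta_total = m$beta_total$beta, beta_xm = m$beta_xm$beta,
    beta_my = m$beta_my$beta, indirect = m$indirect,
    indirect_se = m$indirect_se,
    proportion_pct = 100 * m$proportion,
    proportion_se_pct = 100 * m$proportion_se,
    proportion_ci_low_pct = 100 * m$proportion_ci_low,
    proportion_ci_high_pct = 100 * m$proportion_ci_high)

  if (!is.null(cfg$estimates_file)) {
    est <- .read_prefitted(cfg$estimates_file)
    m <- mediation_effect(est$xm, est$my, est$total,
                          denominator_mode = cfg$screen$denominator_mode)
    tab <- med_row(m)
    utils::write.table(tab, file.path(cfg$out_dir, "mediation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$mode <- "prefitted"
    report$mediation <- as.list(tab)
  } else if (!is.null(cfg$mediators)) {
    if (length(cfg$mediators) == 0L) stop("empty candidate mediator list")
    exposure <- .read_trait(cfg$exposure, "exposure")
    outcome <- .read_trait(cfg$outcome, "outcome")
    ld <- if (!is.null(cfg$ld$path)) read_ld_matrix(cfg$ld$path)
    prep <- .prepare_instruments(exposure, cfg, ld)
    candidates <- list()
    for (cand in cfg$mediators) {
      tab <- read_sumstats(cand$path, column_map = cand$column_map,
                           trait_label = cand$label)
      instr <- if (!is.null(cand$instruments_path)) {
        read_sumstats(cand$instruments_path)$variant_id
      } else {
        p <- .prepare_instruments(tab, cfg, ld)
        p$instruments$variant_id
      }
      candidates[[cand$label]] <- list(sumstats = tab, instruments = instr)
    }
    st <- do.call(screen_mediators,
                  c(list(exposure = exposure, outcome = outcome,
                         candidates = candidates,
                         exposure_instruments = prep$instruments,
                         cfg = cfg$screen),
                    cfg$harmonize))
    write_screen_table(st, file.path(cfg$out_dir, "screen.tsv"))
    report$mode <- "screen"
    report$counts <- prep$counts
    report$n_candidates <- nrow(st)
    report$n_qualifying <- sum(st$qualifies)
    report$n_positive <- attr(st, "n_positive")
    report$n_negative <- attr(st, "n_negative")
  } else if (!is.null(cfg$mediator)) {
    exposure <- .read_trait(cfg$exposure, "exposure")
    mediator <- .read_trait(cfg$mediator, "mediator")
    outcome <- .read_trait(cfg$outcome, "outcome")
    ld <- if (!is.null(cfg$ld$path)) read_ld_matrix(cfg$ld$path)
    prep_x <- .prepare_instruments(exposure, cfg, ld)
    prep_m <- .prepare_instruments(mediator, cfg, ld)
    m <- do.call(two_step_mediation,
                 c(list(exposure = exposure, mediator = mediator,
                        outcome = outcome,
                        exposure_instruments = prep_x$instruments,
                        mediator_instruments = prep_m$instruments,
                        cfg = cfg$screen),
                   cfg$harmonize))
    tab <- med_row(m)
    utils::write.table(tab, file.path(cfg$out_dir, "mediation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$mode <- "two_step"
    report$counts <- list(exposure = prep_x$counts, mediator = prep_m$counts)
    report$mediation <- as.list(tab)
  } else {
    stop("config must provide estimates_file, mediator, or mediators")
  }
  .write_report(report, cfg$out_dir, "mediation_report.json")
  invisible(report)
}
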