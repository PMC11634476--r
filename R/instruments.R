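# Instrument selection: association threshold, greedy LD clumping,
# F-statistic screening.

#' Instrument-selection configuration
#'
#' Defaults follow common drug-target MR practice for eQTL-anchored
#' instruments: association threshold p < 1e-4, prune LD at r^2 > 0.8
#' within a 250 kb window, and require per-variant F > 10.
#'
#' @param p_threshold association p-value threshold (strict `<`).
#' @param r2_max LD r-squared above which a variant is clumped away.
#' @param window_kb clumping window, kilobases (center-to-center).
#' @param f_min weak-instrument F threshold (strict `>` to retain).
#' @return A `selection_config` list.
#' @export
selection_config <- function(p_threshold = 1e-4, r2_max = 0.8,
                             window_kb = 250, f_min = 10) {
  stopifnot(p_threshold > 0, p_threshold <= 1,
            r2_max >= 0, r2_max <= 1, window_kb > 0, f_min >= 0)
  structure(list(p_threshold = p_threshold, r2_max = r2_max,
                 window_kb = window_kb, f_min = f_min),
            class = "selection_config")
}

#' Construct an LD correlation matrix object
#'
#' @param r2 symmetric matrix of r-squared values in \[0, 1\] with unit
#'   diagonal, dimnames matching `variant_ids`.
#' @param variant_ids character vector of variant ids (row/col order).
#' @param positions data.frame with columns `variant_id`, `chrom`, `pos`.
#' @param tol symmetry tolerance.
#' @return An `ld_matrix` list.
#' @export
ld_matrix <- function(r2, variant_ids = rownames(r2), positions = NULL,
                      tol = 1e-8) {
  r2 <- as.matrix(r2)
  if (nrow(r2) != ncol(r2)) stop("LD matrix must be square")
  if (length(variant_ids) != nrow(r2)) stop("variant_ids length must match LD matrix dimension")
  if (any(is.na(r2)) || any(r2 < -tol) || any(r2 > 1 + tol)) {
    stop("LD r2 values must lie in [0, 1]")
  }
  if (max(abs(r2 - t(r2))) > tol) stop("LD matrix is not symmetric")
  if (max(abs(diag(r2) - 1)) > tol) stop("LD matrix diagonal must be 1")
  dimnames(r2) <- list(variant_ids, variant_ids)
  structure(list(r2 = r2, variant_ids = as.character(variant_ids),
                 positions = positions),
            class = "ld_matrix")
}

#' Write an LD matrix and its positions sidecar
#'
#' The matrix file is tab-delimited with a `variant_id` header column; the
#' sidecar holds `variant_id`, `chrom`, `pos`.
#'
#' @param ld an [ld_matrix].
#' @param path matrix file path.
#' @param positions_path sidecar path (default `<path>.positions`).
#' @export
write_ld_matrix <- function(ld, path, positions_path = paste0(path, ".positions")) {
  stopifnot(inherits(ld, "ld_matrix"))
  m <- data.frame(variant_id = ld$variant_ids,
                  apply(ld$r2, 2, function(x) sprintf("%.17g", x)),
                  check.names = FALSE, stringsAsFactors = FALSE)
  names(m) <- c("variant_id", ld$variant_ids)
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(ld$positions)) {
    utils::write.table(ld$positions, positions_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read an LD matrix written by [write_ld_matrix]
#'
#' Validates symmetry within `tol`.
#' @param path matrix file path.
#' @param positions_path sidecar path; read if the file exists.
#' @param tol symmetry tolerance (default 1e-8).
#' @return An [ld_matrix].
#' @export
read_ld_matrix <- function(path, positions_path = paste0(path, ".positions"),
                           tol = 1e-8) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(raw$variant_id)
  r2 <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(r2) <- "double"
  pos <- NULL
  if (file.exists(positions_path)) {
    pos <- utils::read.table(positions_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  }
  ld_matrix(r2, ids, positions = pos, tol = tol)
}

#' Filter variants by association p-value
#'
#' Retains rows with `pval < p_threshold` (strict), preserving input order.
#'
#' @param table a [sumstats] table.
#' @param p_threshold p-value threshold (default 1e-4).
#' @return Filtered [sumstats] table (possibly empty).
#' @export
select_by_pvalue <- function(table, p_threshold = 1e-4) {
  stopifnot(p_threshold > 0, p_threshold <= 1)
  keep <- !is.na(table$pval) & table$pval < p_threshold
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping
#'
#' PLINK-style greedy pruning: candidates are ranked by ascending p-value
#' (ties broken by variant id); the best remaining variant is taken as
#' index and every other remaining variant on the same chromosome within
#' `window_kb` and with r^2 > `r2_max` against it is removed. Variants
#' absent from the LD matrix are retained and never pruned (with a
#' warning). The retained set is returned in the original table order and
#' is independent of input row order.
#'
#' @param table a [sumstats] table with `chrom`/`pos` filled in.
#' @param ld an [ld_matrix] covering (at least) the table's variants.
#' @param r2_max prune when r^2 exceeds this (default 0.8).
#' @param window_kb window in kb (default 250).
#' @return Clumped [sumstats] table.
#' @export
clump <- function(table, ld, r2_max = 0.8, window_kb = 250) {
  stopifnot(inherits(ld, "ld_matrix"), r2_max >= 0, r2_max <= 1, window_kb > 0)
  if (nrow(table) == 0L) return(table)
  missing_ld <- setdiff(table$variant_id, ld$variant_ids)
  if (length(missing_ld) > 0L) {
    warning(length(missing_ld), " variant(s) absent from the LD matrix pass through unclumped")
  }
  ord <- order(ifelse(is.na(table$pval), Inf, table$pval), table$variant_id)
  ids <- table$variant_id[ord]
  chrom <- table$chrom[ord]
  pos <- table$pos[ord]
  window_bp <- window_kb * 1000

  r2_of <- function(a, b) {
    if (a %in% ld$variant_ids && b %in% ld$variant_ids) ld$r2[a, b] else 0
  }
  alive <- rep(TRUE, length(ids))
  retained <- character(0)
  for (i in seq_along(ids)) {
    if (!alive[i]) next
    retained <- c(retained, ids[i])
    alive[i] <- FALSE
    if (i == length(ids)) break
    for (j in seq_along(ids)) {
      if (!alive[j]) next
      if (is.na(chrom[i]) || is.na(chrom[j]) || chrom[i] != chrom[j]) next
      if (is.na(pos[i]) || is.na(pos[j])) next
      if (abs(pos[i] - pos[j]) > window_bp) next
      if (r2_of(ids[i], ids[j]) > r2_max) alive[j] <- FALSE
    }
  }
  out <- table[table$variant_id %in% retained, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Instrument strength (F statistics)
#'
#' Per-variant F = (beta / se)^2; `mean_F` is the arithmetic mean and
#' `n_weak` counts variants with F < `f_min`.
#'
#' @param table a [sumstats] table.
#' @param f_min weak-instrument threshold (default 10).
#' @return An `instrument_strength` list with `F` (named vector),
#'   `mean_F`, `n_weak`.
#' @export
f_statistics <- function(table, f_min = 10) {
  F <- (table$beta / table$se)^2
  names(F) <- table$variant_id
  structure(list(F = F,
                 mean_F = if (length(F)) mean(F) else NA_real_,
                 n_weak = sum(F < f_min)),
            class = "instrument_strength")
}

#' Drop weak instruments
#'
#' Retains rows with F = (beta/se)^2 strictly greater than `f_min`.
#'
#' @param table a [sumstats] table.
#' @param f_min F threshold (default 10).
#' @return Filtered [sumstats] table; errors if nothing survives.
#' @export
filter_weak <- function(table, f_min = 10) {
  F <- (table$beta / table$se)^2
  out <- table[F > f_min, , drop = FALSE]
  if (nrow(out) == 0L) stop("no instruments survive F filter")
  rownames(out) <- NULL
  out
}
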