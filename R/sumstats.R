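# Canonical column order of the on-disk summary-statistics dialect.
SUMSTATS_COLUMNS <- c("variant_id", "chrom", "pos", "effect_allele",
                      "other_allele", "eaf", "beta", "se", "pval", "n")

# Header aliases accepted on ingestion (GWAS-SSF-like names and common
# variants). Matched case-insensitively after the user column_map.
.sumstats_aliases <- list(
  variant_id    = c("variant_id", "rsid", "rs_id", "snp", "markername", "id"),
  chrom         = c("chrom", "chromosome", "chr"),
  pos           = c("pos", "position", "base_pair_location", "bp"),
  effect_allele = c("effect_allele", "ea", "a1", "allele1"),
  other_allele  = c("other_allele", "oa", "a2", "allele2",
                    "reference_allele", "non_effect_allele"),
  eaf           = c("eaf", "effect_allele_frequency", "freq", "af", "maf"),
  beta          = c("beta", "effect", "b"),
  se            = c("se", "standard_error", "stderr"),
  pval          = c("pval", "p_value", "p", "pvalue"),
  n             = c("n", "sample_size", "n_total")
)

.mandatory_cols <- c("variant_id", "effect_allele", "other_allele", "beta", "se")

#' Construct a validated summary-statistics table
#'
#' A `sumstats` object is a data.frame with one row per variant and the
#' canonical columns `variant_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`. Rows violating the
#' record invariants (alleles in \{A,C,G,T\} and distinct, `se > 0`,
#' `pval` in (0, 1], `eaf` in (0, 1) when present) are dropped with a
#' warning; duplicated `variant_id`s keep the lowest-p row.
#'
#' @param df data.frame holding (at least) the mandatory columns
#'   `variant_id`, `effect_allele`, `other_allele`, `beta`, `se`.
#' @param trait_label character scalar naming the trait.
#' @param quiet suppress the dropped-row warning.
#' @return A `sumstats` data.frame with attributes `trait_label` and
#'   `n_dropped` (rows removed by validation).
#' @export
sumstats <- function(df, trait_label = "trait", quiet = FALSE) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(.mandatory_cols, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    variant_id    = as.character(df$variant_id),
    chrom         = if ("chrom" %in% names(df)) as.character(df$chrom) else NA_character_,
    pos           = if ("pos" %in% names(df)) suppressWarnings(as.integer(df$pos)) else NA_integer_,
    effect_allele = toupper(as.character(df$effect_allele)),
    other_allele  = toupper(as.character(df$other_allele)),
    eaf           = if ("eaf" %in% names(df)) suppressWarnings(as.numeric(df$eaf)) else NA_real_,
    beta          = suppressWarnings(as.numeric(df$beta)),
    se            = suppressWarnings(as.numeric(df$se)),
    pval          = if ("pval" %in% names(df)) suppressWarnings(as.numeric(df$pval)) else NA_real_,
    n             = if ("n" %in% names(df)) suppressWarnings(as.numeric(df$n)) else NA_real_,
    stringsAsFactors = FALSE
  )

  valid_allele <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")
  ok <- !is.na(out$variant_id) & nzchar(out$variant_id) &
    valid_allele(out$effect_allele) & valid_allele(out$other_allele) &
    out$effect_allele != out$other_allele &
    !is.na(out$beta) & is.finite(out$beta) &
    !is.na(out$se) & out$se > 0 &
    (is.na(out$pval) | (out$pval > 0 & out$pval <= 1)) &
    (is.na(out$eaf) | (out$eaf > 0 & out$eaf < 1))
  n_dropped <- sum(!ok)
  out <- out[ok, , drop = FALSE]

  # duplicated ids: keep the lowest p-value row (NA p last), deterministic
  if (anyDuplicated(out$variant_id)) {
    p_order <- ifelse(is.na(out$pval), Inf, out$pval)
    keep <- order(p_order, seq_len(nrow(out)))
    out <- out[keep, , drop = FALSE]
    dup <- duplicated(out$variant_id)
    if (!quiet) warning(sum(dup), " duplicated variant_id(s); kept lowest p-value row")
    out <- out[!dup, , drop = FALSE]
    out <- out[order(match(out$variant_id, df$variant_id)), , drop = FALSE]
  }
  rownames(out) <- NULL
  structure(out,
            trait_label = trait_label,
            n_dropped = n_dropped,
            class = c("sumstats", "data.frame"))
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> trait '%s': %d variants (%d dropped at read)\n",
              attr(x, "trait_label") %||% "?", nrow(x), attr(x, "n_dropped") %||% 0L))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.resolve_columns <- function(headers, column_map) {
  res <- list()
  lower <- tolower(headers)
  for (canon in SUMSTATS_COLUMNS) {
    hit <- NA_integer_
    if (!is.null(column_map) && canon %in% names(column_map)) {
      hit <- match(column_map[[canon]], headers)
      if (is.na(hit)) stop("column_map names '", column_map[[canon]],
                           "' for ", canon, " but the file has no such column")
    } else {
      for (alias in .sumstats_aliases[[canon]]) {
        hit <- match(alias, lower)
        if (!is.na(hit)) break
      }
    }
    if (!is.na(hit)) res[[canon]] <- hit
  }
  res
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Accepts tab- or comma-delimited files with a header row. Canonical
#' column names (and common aliases such as `rsid`, `p_value`,
#' `standard_error`) are recognized automatically; `column_map` overrides
#' the mapping for nonstandard headers. Rows failing validation are
#' dropped and counted in the `n_dropped` attribute.
#'
#' @param path file path.
#' @param column_map optional named list/character vector mapping canonical
#'   field names (`variant_id`, `beta`, ...) to the file's column headers.
#' @param trait_label trait name stored on the returned table.
#' @return A [sumstats] table.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           comment.char = "", check.names = FALSE,
                           na.strings = c("NA", ""))
  idx <- .resolve_columns(names(raw), column_map)
  missing_cols <- setdiff(.mandatory_cols, names(idx))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- stats::setNames(raw[unlist(idx)], names(idx))
  sumstats(df, trait_label = trait_label)
}

#' Write a summary-statistics table in the canonical dialect
#'
#' Tab-delimited, canonical header, missing values as `NA`, numeric fields
#' at 17 significant digits so a read/write round trip is bit-exact.
#'
#' @param table a [sumstats] table.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_sumstats <- function(table, path) {
  stopifnot(inherits(table, "sumstats") || is.data.frame(table))
  fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  fmt_chr <- function(x) ifelse(is.na(x), "NA", as.character(x))
  out <- data.frame(
    variant_id    = fmt_chr(table$variant_id),
    chrom         = fmt_chr(table$chrom),
    pos           = fmt_chr(table$pos),
    effect_allele = fmt_chr(table$effect_allele),
    other_allele  = fmt_chr(table$other_allele),
    eaf           = fmt_num(table$eaf),
    beta          = fmt_num(table$beta),
    se            = fmt_num(table$se),
    pval          = fmt_num(table$pval),
    n             = fmt_num(table$n),
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) stop("cannot write to ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' Is an allele pair palindromic?
#'
#' A/T and C/G pairs read the same on both strands, so strand cannot be
#' resolved from the alleles alone.
#'
#' @param effect_allele,other_allele single-letter alleles in \{A,C,G,T\}
#'   (vectorized).
#' @return Logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  ea <- toupper(effect_allele)
  oa <- toupper(other_allele)
  if (any(!ea %in% c("A", "C", "G", "T")) || any(!oa %in% c("A", "C", "G", "T"))) {
    stop("alleles must be one of A, C, G, T")
  }
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

#' Harmonize exposure and outcome summary statistics to a shared effect allele
#'
#' For every variant present in both tables, the outcome association is
#' re-expressed on the exposure's effect allele: identical allele pairs are
#' kept as-is; swapped (or strand-complement-swapped) pairs have the
#' outcome beta negated and the outcome EAF complemented and are flagged
#' `flipped`; incompatible pairs are dropped. Palindromic (A/T, C/G)
#' variants cannot be resolved by allele matching and are handled per
#' `palindrome_policy`:
#' \describe{
#'   \item{`drop_all`}{drop every palindromic variant.}
#'   \item{`drop_ambiguous`}{(default) drop palindromic variants whose EAF
#'     is missing or within `eaf_ambiguity_band` of 0.5 in either table;
#'     orient the remainder by matching the minor/major-allele side of the
#'     two EAFs.}
#'   \item{`keep`}{align palindromic variants by nominal allele match, like
#'     any other variant.}
#' }
#'
#' @param exposure,outcome [sumstats] tables.
#' @param palindrome_policy one of `"drop_ambiguous"`, `"drop_all"`, `"keep"`.
#' @param eaf_ambiguity_band half-width of the EAF band around 0.5 inside
#'   which a palindromic variant is considered unresolvable (default 0.08,
#'   i.e. drop when 0.42 <= EAF <= 0.58).
#' @return A `harmonized_set`: data.frame with columns `variant_id`,
#'   `gamma`, `se_gamma` (SNP-exposure effect and SE), `Gamma`, `se_Gamma`
#'   (SNP-outcome), `eaf`, `flipped`, `palindromic`, sorted by
#'   `variant_id`, with `exposure_label`/`outcome_label` attributes.
#' @export
harmonize_pair <- function(exposure, outcome,
                           palindrome_policy = c("drop_ambiguous", "drop_all", "keep"),
                           eaf_ambiguity_band = 0.08) {
  palindrome_policy <- match.arg(palindrome_policy)
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  if (length(shared) == 0L) stop("no shared instruments")
  ex <- exposure[match(shared, exposure$variant_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$variant_id), , drop = FALSE]

  n <- length(shared)
  keep <- rep(TRUE, n)
  flip <- rep(FALSE, n)
  pal <- is_palindromic(ex$effect_allele, ex$other_allele)

  same  <- ou$effect_allele == ex$effect_allele & ou$other_allele == ex$other_allele
  swap  <- ou$effect_allele == ex$other_allele & ou$other_allele == ex$effect_allele
  csame <- .complement[ou$effect_allele] == ex$effect_allele &
           .complement[ou$other_allele] == ex$other_allele
  cswap <- .complement[ou$effect_allele] == ex$other_allele &
           .complement[ou$other_allele] == ex$effect_allele

  for (i in seq_len(n)) {
    if (pal[i]) {
      if (palindrome_policy == "drop_all") {
        keep[i] <- FALSE
      } else if (palindrome_policy == "keep") {
        if (same[i]) {
          # as-is
        } else if (swap[i]) {
          flip[i] <- TRUE
        } else keep[i] <- FALSE
      } else { # drop_ambiguous: resolve orientation through allele frequency
        fe <- ex$eaf[i]; fo <- ou$eaf[i]
        ambiguous <- is.na(fe) || is.na(fo) ||
          abs(fe - 0.5) <= eaf_ambiguity_band || abs(fo - 0.5) <= eaf_ambiguity_band
        if (ambiguous || !(same[i] || swap[i] || csame[i] || cswap[i])) {
          keep[i] <- FALSE
        } else {
          # same minor/major side of 0.5: same effect allele; opposite: flipped
          flip[i] <- (fe < 0.5) != (fo < 0.5)
        }
      }
    } else {
      if (same[i] || csame[i]) {
        # as-is
      } else if (swap[i] || cswap[i]) {
        flip[i] <- TRUE
      } else keep[i] <- FALSE
    }
  }

  Gamma <- ifelse(flip, -ou$beta, ou$beta)
  eaf_out <- ifelse(flip, 1 - ou$eaf, ou$eaf)
  h <- data.frame(
    variant_id = shared,
    gamma = ex$beta, se_gamma = ex$se,
    Gamma = Gamma, se_Gamma = ou$se,
    eaf = ex$eaf, eaf_outcome = eaf_out,
    flipped = flip, palindromic = pal,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  if (nrow(h) == 0L) stop("all shared variants dropped during harmonization")
  h <- h[order(h$variant_id), , drop = FALSE]
  rownames(h) <- NULL
  structure(h,
            exposure_label = attr(exposure, "trait_label") %||% "exposure",
            outcome_label = attr(outcome, "trait_label") %||% "outcome",
            class = c("harmonized_set", "data.frame"))
}

#' Construct a harmonized set from raw effect vectors
#'
#' Convenience constructor used by the estimators and simulations when the
#' per-variant effects are already on a shared effect allele.
#'
#' @param gamma,se_gamma SNP-exposure effects and standard errors.
#' @param Gamma,se_Gamma SNP-outcome effects and standard errors.
#' @param variant_id optional ids (defaults `snp1..snpJ`).
#' @param exposure_label,outcome_label trait names.
#' @return A `harmonized_set` data.frame.
#' @export
harmonized_set <- function(gamma, se_gamma, Gamma, se_Gamma,
                           variant_id = NULL,
                           exposure_label = "exposure",
                           outcome_label = "outcome") {
  J <- length(gamma)
  stopifnot(length(se_gamma) == J, length(Gamma) == J, length(se_Gamma) == J,
            J >= 1, all(se_gamma > 0), all(se_Gamma > 0))
  if (is.null(variant_id)) variant_id <- sprintf("snp%03d", seq_len(J))
  structure(
    data.frame(variant_id = variant_id, gamma = gamma, se_gamma = se_gamma,
               Gamma = Gamma, se_Gamma = se_Gamma, eaf = NA_real_,
               eaf_outcome = NA_real_, flipped = FALSE, palindromic = FALSE,
               stringsAsFactors = FALSE),
    exposure_label = exposure_label, outcome_label = outcome_label,
    class = c("harmonized_set", "data.frame"))
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s: %d instruments (%d flipped, %d palindromic)\n",
              attr(x, "exposure_label"), attr(x, "outcome_label"),
              nrow(x), sum(x$flipped), sum(x$palindromic)))
  NextMethod()
}
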