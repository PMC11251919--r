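#  Data model and I/O for GWAS summary statistics, plus instrument selection
#  by significance, independence (clumping) and strength (F statistics).

SUMSTATS_COLUMNS <- c(
  "variant_id", "chromosome", "position", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pvalue", "n"
)
MANDATORY_COLUMNS <- c(
  "variant_id", "effect_allele", "other_allele", "beta", "se", "pvalue"
)
BASES <- c("A", "C", "G", "T")

#' Column-name mapping for summary-statistics files
#'
#' Maps the package's internal field names to the column headers of a
#' delimited summary-statistics file. Defaults follow the common
#' `SNP / effect_allele / other_allele / eaf / beta / se / pval / n` layout.
#'
#' @param variant_id,chromosome,position,effect_allele,other_allele,eaf,beta,se,pvalue,n
#'   Column header holding each field.
#' @return A named list usable as the `dialect` argument of
#'   [read_sumstats()] and [write_sumstats()].
#' @export
#' @examples
#' sumstats_dialect(variant_id = "rsid", pvalue = "p")
sumstats_dialect <- function(variant_id = "SNP",
                             chromosome = "chr",
                             position = "pos",
                             effect_allele = "effect_allele",
                             other_allele = "other_allele",
                             eaf = "eaf",
                             beta = "beta",
                             se = "se",
                             pvalue = "pval",
                             n = "n") {
  list(
    variant_id = variant_id, chromosome = chromosome, position = position,
    effect_allele = effect_allele, other_allele = other_allele, eaf = eaf,
    beta = beta, se = se, pvalue = pvalue, n = n
  )
}

#' Construct a validated summary-statistics dataset
#'
#' Builds a `summary_dataset`: a data frame of per-variant associations for
#' one trait, validated, de-duplicated, and sorted by genomic position.
#' Rows violating the invariants (alleles outside A/C/G/T or identical,
#' non-positive `se`, `pvalue` outside (0, 1], `eaf` outside \[0, 1\]) are
#' dropped with a message; the drop count is kept in the `n_dropped`
#' attribute. Reported p-values deviating more than 10% (relative) from the
#' normal-approximation p implied by `beta/se` trigger a warning but are
#' kept — downstream computation always uses `beta` and `se`.
#'
#' @param records Data frame with at least `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pvalue`; optionally `chromosome`,
#'   `position`, `eaf`, `n`.
#' @param trait_name Name of the trait.
#' @param trait_type `"continuous"` or `"binary"` (binary traits carry
#'   log-odds effects).
#' @param n_total GWAS sample size; defaults to the maximum of the `n`
#'   column when present.
#' @param validate Set `FALSE` to skip row validation (trusted input).
#' @return A `summary_dataset` (data frame subclass) with attributes
#'   `trait_name`, `trait_type`, `n_total`, `n_dropped`.
#' @export
summary_dataset <- function(records, trait_name = "trait",
                            trait_type = c("continuous", "binary"),
                            n_total = NULL, validate = TRUE) {
  trait_type <- match.arg(trait_type)
  if (!is.data.frame(records)) stop("`records` must be a data frame")
  missing_cols <- setdiff(MANDATORY_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(SUMSTATS_COLUMNS, names(records))) records[[col]] <- NA
  records <- records[SUMSTATS_COLUMNS]
  records$variant_id <- as.character(records$variant_id)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("position", "eaf", "beta", "se", "pvalue", "n")) {
    records[[col]] <- suppressWarnings(as.numeric(records[[col]]))
  }

  n_dropped <- 0L
  if (validate && nrow(records)) {
    ok <- !is.na(records$variant_id) & nzchar(records$variant_id) &
      records$effect_allele %in% BASES &
      records$other_allele %in% BASES &
      records$effect_allele != records$other_allele &
      is.finite(records$beta) &
      is.finite(records$se) & records$se > 0 &
      is.finite(records$pvalue) & records$pvalue > 0 & records$pvalue <= 1 &
      (is.na(records$eaf) | (records$eaf >= 0 & records$eaf <= 1)) &
      (is.na(records$n) | records$n > 0)
    n_dropped <- sum(!ok)
    if (n_dropped > 0) {
      message(sprintf("summary_dataset('%s'): dropped %d invalid record(s)",
                      trait_name, n_dropped))
      records <- records[ok, , drop = FALSE]
    }
    dup <- duplicated(records$variant_id)
    if (any(dup)) {
      message(sprintf("summary_dataset('%s'): dropped %d duplicated variant id(s)",
                      trait_name, sum(dup)))
      n_dropped <- n_dropped + sum(dup)
      records <- records[!dup, , drop = FALSE]
    }
    # p-value vs z-score consistency (normal approximation, 10% relative)
    p_z <- 2 * pnorm(-abs(records$beta / records$se))
    comparable <- is.finite(p_z) & p_z > 1e-280
    bad <- comparable & abs(records$pvalue - p_z) / p_z > 0.10
    if (any(bad)) {
      warning(sprintf(
        "summary_dataset('%s'): %d record(s) have p-values inconsistent with beta/se (>10%% relative); kept, beta/se preferred",
        trait_name, sum(bad)), call. = FALSE)
    }
  }

  ord <- order(chrom_rank(records$chromosome), records$position,
               records$variant_id, na.last = TRUE)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL

  if (is.null(n_total)) {
    n_total <- if (any(is.finite(records$n))) max(records$n, na.rm = TRUE) else NA_real_
  }
  structure(records,
            trait_name = trait_name, trait_type = trait_type,
            n_total = n_total, n_dropped = n_dropped,
            class = c("summary_dataset", "data.frame"))
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("<summary_dataset> trait '%s' (%s), %d variant(s), n_total = %s\n",
              attr(x, "trait_name"), attr(x, "trait_type"), nrow(x),
              format(attr(x, "n_total"))))
  if (nrow(x)) print(head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more row(s)\n", nrow(x) - 6L))
  invisible(x)
}

#  Row subset preserving class and attributes (rows assumed already sorted).
ds_subset <- function(ds, i) {
  out <- as.data.frame(ds)[i, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            trait_name = attr(ds, "trait_name"),
            trait_type = attr(ds, "trait_type"),
            n_total = attr(ds, "n_total"),
            n_dropped = attr(ds, "n_dropped"),
            class = c("summary_dataset", "data.frame"))
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab-, comma- or whitespace-delimited file with a header row,
#' renames columns through `dialect`, and validates the result via
#' [summary_dataset()].
#'
#' @param path File path.
#' @param dialect Column-name mapping from [sumstats_dialect()].
#' @param trait_name Trait name; defaults to the file name without extension.
#' @inheritParams summary_dataset
#' @return A `summary_dataset`.
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect(),
                          trait_name = NULL,
                          trait_type = c("continuous", "binary"),
                          n_total = NULL) {
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character())
  if (!length(first) || !nzchar(first)) stop("input error: empty file: ", path)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  if (!nrow(df)) stop("input error: no data rows in ", path)
  for (field in MANDATORY_COLUMNS) {
    if (!dialect[[field]] %in% names(df)) {
      stop(sprintf("configuration error: required column '%s' (field '%s') not found in %s",
                   dialect[[field]], field, path))
    }
  }
  records <- data.frame(row.names = seq_len(nrow(df)))
  for (field in SUMSTATS_COLUMNS) {
    col <- dialect[[field]]
    records[[field]] <- if (!is.null(col) && col %in% names(df)) df[[col]] else NA
  }
  if (is.null(trait_name)) {
    trait_name <- sub("\\.[^.]*$", "", basename(path))
  }
  summary_dataset(records, trait_name = trait_name,
                  trait_type = match.arg(trait_type), n_total = n_total)
}

#' Write a summary-statistics dataset as delimited text
#'
#' @param ds A `summary_dataset`.
#' @param path Output file path.
#' @param dialect Column-name mapping (written headers).
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ds, path, dialect = sumstats_dialect(), sep = "\t") {
  out <- as.data.frame(ds)
  names(out) <- vapply(names(out), function(f) dialect[[f]] %||% f, character(1))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select instruments by p-value threshold
#'
#' Keeps variants with `pvalue < p_threshold` (strict), preserving order.
#' A typical workflow uses the genome-wide threshold 5e-8 where instruments
#' are plentiful, a relaxed 1e-5 for traits with few genome-wide hits
#' (microbiome taxa, metabolites), and 5e-5 for reverse-direction analyses
#' that need larger instrument counts.
#'
#' @param ds A `summary_dataset`.
#' @param p_threshold Significance threshold in (0, 1).
#' @return A `summary_dataset` subset. An empty selection warns rather than
#'   errors so batch pipelines can decide how to proceed.
#' @export
select_instruments <- function(ds, p_threshold = 1e-5) {
  stopifnot(inherits(ds, "summary_dataset"))
  if (!is.numeric(p_threshold) || length(p_threshold) != 1L ||
      !is.finite(p_threshold) || p_threshold <= 0 || p_threshold >= 1) {
    stop("`p_threshold` must be a single number in (0, 1)")
  }
  keep <- which(ds$pvalue < p_threshold)
  if (!length(keep)) {
    warning(sprintf("no instruments for '%s' at p < %g",
                    attr(ds, "trait_name"), p_threshold), call. = FALSE)
  }
  ds_subset(ds, keep)
}

#  r^2 between two variants from a symmetric LD matrix with variant ids as
#  dimnames; pairs absent from the matrix are treated as independent (0).
ld_r2 <- function(ld, id_a, id_b) {
  if (is.null(ld)) return(NA_real_)
  ids <- rownames(ld)
  ia <- rep_len(match(id_a, ids), length(id_b))
  ib <- match(id_b, ids)
  out <- rep(0, length(ib))
  ok <- !is.na(ia) & !is.na(ib)
  if (any(ok)) out[ok] <- ld[cbind(ia[ok], ib[ok])]
  out
}

#' Greedy LD clumping of instruments
#'
#' Repeatedly takes the smallest-p remaining variant as an index and removes
#' all remaining variants on the same chromosome within `window_bp` of it
#' whose r-squared with the index is at least `r2_max`. When no LD
#' information is supplied, every variant within the window is removed
#' (distance-only clumping) and a message is logged. Ties in p-value are
#' broken by (chromosome, position, variant id) so the result does not
#' depend on input row order. Windows never span chromosomes; distance is
#' `|pos_a - pos_b| <= window_bp` on 1-based positions.
#'
#' @param ds A `summary_dataset` (typically the output of
#'   [select_instruments()]).
#' @param ld Optional symmetric matrix of pairwise r-squared values with
#'   variant ids as dimnames. Pairs missing from the matrix are treated as
#'   independent.
#' @param window_bp Clumping window in base pairs (default 10 Mb).
#' @param r2_max r-squared threshold at or above which a variant is removed
#'   (default 0.001).
#' @return A `summary_dataset` of index variants.
#' @export
clump_instruments <- function(ds, ld = NULL, window_bp = 1e7, r2_max = 0.001) {
  stopifnot(inherits(ds, "summary_dataset"))
  if (!is.numeric(window_bp) || window_bp <= 0) stop("`window_bp` must be > 0")
  if (!is.numeric(r2_max) || r2_max < 0 || r2_max >= 1) {
    stop("`r2_max` must be in [0, 1)")
  }
  if (nrow(ds) < 2L) return(ds)
  if (is.null(ld)) {
    message("clump_instruments: no LD supplied; distance-only clumping within window")
  }
  chr_key <- chrom_rank(ds$chromosome)
  pos <- ds$position
  ord <- order(ds$pvalue, chr_key, pos, ds$variant_id, na.last = TRUE)
  alive <- rep(TRUE, nrow(ds))
  kept <- logical(nrow(ds))
  for (i in ord) {
    if (!alive[i]) next
    kept[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive & !is.na(chr_key) & chr_key == chr_key[i] &
                    !is.na(pos) & abs(pos - pos[i]) <= window_bp)
    if (!length(cand)) next
    if (is.null(ld)) {
      alive[cand] <- FALSE
    } else {
      r2 <- ld_r2(ld, ds$variant_id[i], ds$variant_id[cand])
      alive[cand[r2 >= r2_max]] <- FALSE
    }
  }
  ds_subset(ds, which(kept))
}

#' Per-variant proportion of trait variance explained
#'
#' For a standardized (unit-variance) trait, the variance explained by one
#' biallelic variant is `2 * eaf * (1 - eaf) * beta^2`; values are clipped
#' to \[0, 1). Summing over independent instruments gives the aggregate
#' R-squared used by [f_statistic()].
#'
#' @param v A `summary_dataset` or data frame with `eaf` and `beta` columns.
#' @return Numeric vector of per-variant R-squared values.
#' @export
#' @examples
#' variance_explained(data.frame(eaf = 0.5, beta = 0.2))  # 0.02
variance_explained <- function(v) {
  if (!is.data.frame(v) || !all(c("eaf", "beta") %in% names(v))) {
    stop("`v` must be a data frame with `eaf` and `beta` columns")
  }
  if (anyNA(v$eaf)) {
    stop("eaf is missing for some variants; supply eaf (or per-variant r2) to compute variance explained")
  }
  r2 <- 2 * v$eaf * (1 - v$eaf) * v$beta^2
  pmin(pmax(r2, 0), 1 - 1e-15)
}

#' Instrument-strength F statistic
#'
#' Computes `F = R2 * (n - k - 1) / (k * (1 - R2))` for `k` instruments
#' jointly explaining a proportion `R2` of exposure variance in a GWAS of
#' size `n`. `F > 10` is the conventional bar for "no substantial
#' weak-instrument bias"; the `weak` flag is `TRUE` when `F <= 10`.
#'
#' @param r2_total Proportion of variance explained, in \[0, 1).
#' @param n GWAS sample size (`n > k + 1`).
#' @param k Number of instruments (`k >= 1`).
#' @return An `instrument_strength` object with fields `r2_total`, `n`, `k`,
#'   `f_stat`, `weak`.
#' @export
#' @examples
#' f_statistic(0.5, 102, 1)  # F = 100
f_statistic <- function(r2_total, n, k) {
  stopifnot(is.numeric(r2_total), length(r2_total) == 1L,
            is.numeric(n), length(n) == 1L, is.numeric(k), length(k) == 1L)
  if (r2_total < 0 || r2_total >= 1) stop("`r2_total` must be in [0, 1)")
  if (k < 1) stop("`k` must be >= 1")
  if (n <= k + 1) stop("domain error: need n > k + 1")
  f <- r2_total * (n - k - 1) / (k * (1 - r2_total))
  structure(list(r2_total = r2_total, n = n, k = k, f_stat = f,
                 weak = f <= 10),
            class = "instrument_strength")
}

#' @export
print.instrument_strength <- function(x, ...) {
  cat(sprintf("<instrument_strength> R2 = %.4g over k = %d instrument(s), n = %g: F = %.2f%s\n",
              x$r2_total, x$k, x$n, x$f_stat,
              if (x$weak) " (weak: F <= 10)" else ""))
  invisible(x)
}

#' Instrument strength of a selected instrument set
#'
#' Convenience wrapper: sums [variance_explained()] over the (assumed
#' independent) instruments of `ds` and applies [f_statistic()] with
#' `k = nrow(ds)`. With `per_snp = TRUE` returns instead a table of
#' per-variant R-squared and single-instrument F values (`k = 1`).
#'
#' @param ds A `summary_dataset` of instruments with `eaf` present.
#' @param n Sample size; defaults to the dataset's `n_total`.
#' @param per_snp Return per-variant values instead of the aggregate.
#' @return An `instrument_strength`, or a data frame when `per_snp = TRUE`.
#' @export
instrument_strength <- function(ds, n = NULL, per_snp = FALSE) {
  stopifnot(inherits(ds, "summary_dataset"))
  n <- n %||% attr(ds, "n_total")
  if (is.null(n) || !is.finite(n)) stop("sample size `n` unavailable")
  r2 <- variance_explained(ds)
  if (per_snp) {
    return(data.frame(variant_id = ds$variant_id, r2 = r2,
                      f_stat = r2 * (n - 2) / (1 - r2)))
  }
  f_statistic(sum(r2), n = n, k = nrow(ds))
}
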