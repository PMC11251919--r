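#  Alignment of exposure and outcome summary statistics to a shared effect
#  allele, with removal of palindromic and incompatible variants.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Is an allele pair palindromic?
#'
#' A variant is palindromic (ambiguous) when its two alleles are strand
#' complements of each other — A/T or C/G — so the effect allele cannot be
#' matched across studies without strand information.
#'
#' @param effect_allele,other_allele Character vectors of single bases.
#' @return Logical vector.
#' @export
#' @examples
#' is_palindromic("A", "T")  # TRUE
#' is_palindromic("A", "G")  # FALSE
is_palindromic <- function(effect_allele, other_allele) {
  a <- toupper(effect_allele)
  b <- toupper(other_allele)
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' Harmonize exposure instruments with outcome summary statistics
#'
#' Matches the exposure instruments into the outcome dataset by variant id
#' and expresses both effects per copy of the exposure's effect allele.
#' For each matched variant: identical allele pairs in the same orientation
#' are kept as-is; the same pair in swapped orientation has the outcome
#' effect negated and its frequency flipped; pairs that match only after
#' strand complementation are complemented first and then aligned the same
#' way; palindromic (A/T, C/G) variants are removed by default since their
#' strand cannot be resolved; anything else is removed as incompatible.
#' Unmatched instruments are dropped.
#'
#' With `palindromic = "infer"`, palindromic variants whose effect-allele
#' frequencies are informative in both studies (both outside the ambiguity
#' band, default 0.30–0.70) are aligned by matching minor-allele side;
#' palindromic variants inside the band are still removed.
#'
#' @param exposure `summary_dataset` of exposure instruments.
#' @param outcome `summary_dataset` of outcome associations.
#' @param palindromic `"drop"` (default) or `"infer"`.
#' @param ambiguity_band Frequency band within which palindromic inference
#'   is refused.
#' @return A `harmonized_instruments` data frame (columns `variant_id`,
#'   `effect_allele`, `other_allele`, `beta_exposure`, `se_exposure`,
#'   `eaf_exposure`, `pval_exposure`, `beta_outcome`, `se_outcome`,
#'   `eaf_outcome`, `pval_outcome`) with a `log` attribute whose counts
#'   (`n_matched`, `n_palindromic_removed`, `n_incompatible_removed`,
#'   `n_unmatched`) partition `n_input` exactly; `n_flipped` counts the
#'   subset of matched variants whose outcome orientation was reversed.
#' @export
harmonize_pair <- function(exposure, outcome,
                           palindromic = c("drop", "infer"),
                           ambiguity_band = c(0.30, 0.70)) {
  palindromic <- match.arg(palindromic)
  stopifnot(inherits(exposure, "summary_dataset"),
            inherits(outcome, "summary_dataset"))
  exposure_name <- attr(exposure, "trait_name")
  outcome_name <- attr(outcome, "trait_name")

  n_input <- nrow(exposure)
  m <- match(exposure$variant_id, outcome$variant_id)
  matched <- !is.na(m)
  n_unmatched <- sum(!matched)
  e <- as.data.frame(exposure)[matched, , drop = FALSE]
  o <- as.data.frame(outcome)[m[matched], , drop = FALSE]

  n_kept <- 0L; n_flipped <- 0L; n_pal <- 0L; n_incomp <- 0L
  out <- NULL
  if (nrow(e)) {
    pal <- is_palindromic(e$effect_allele, e$other_allele)
    same <- o$effect_allele == e$effect_allele & o$other_allele == e$other_allele
    swap <- o$effect_allele == e$other_allele & o$other_allele == e$effect_allele
    c_ea <- unname(COMPLEMENT[o$effect_allele])
    c_oa <- unname(COMPLEMENT[o$other_allele])
    csame <- !same & !swap & c_ea == e$effect_allele & c_oa == e$other_allele
    cswap <- !same & !swap & c_ea == e$other_allele & c_oa == e$effect_allele

    action <- rep("incompatible", nrow(e))
    action[same | csame] <- "keep"
    action[swap | cswap] <- "flip"

    if (palindromic == "drop") {
      action[pal] <- "palindromic"
    } else {
      # infer strand for palindromic variants from allele frequency: letters
      # cannot identify the strand, so align by minor-allele side; a strand
      # flip negates the letter-aligned effect once more
      for (j in which(pal)) {
        if (!(same[j] || swap[j])) { action[j] <- "incompatible"; next }
        q_e <- e$eaf[j]
        q_o <- if (same[j]) o$eaf[j] else 1 - o$eaf[j]  # letter-aligned
        informative <- !is.na(q_e) && !is.na(q_o) &&
          (q_e < ambiguity_band[1] || q_e > ambiguity_band[2]) &&
          (q_o < ambiguity_band[1] || q_o > ambiguity_band[2])
        if (!informative) { action[j] <- "palindromic"; next }
        strand_flip <- (q_e < 0.5) != (q_o < 0.5)
        action[j] <- if (xor(swap[j], strand_flip)) "flip" else "keep"
      }
    }

    keep_rows <- action %in% c("keep", "flip")
    n_pal <- sum(action == "palindromic")
    n_incomp <- sum(action == "incompatible")
    n_flipped <- sum(action == "flip")
    n_kept <- sum(keep_rows)

    if (n_kept) {
      ek <- e[keep_rows, , drop = FALSE]
      ok <- o[keep_rows, , drop = FALSE]
      flip <- action[keep_rows] == "flip"
      beta_out <- ifelse(flip, -ok$beta, ok$beta)
      eaf_out <- ifelse(flip, 1 - ok$eaf, ok$eaf)
      both_pos <- is.finite(ek$position) & is.finite(ok$position)
      mismatch <- both_pos & (ek$position != ok$position)
      if (any(mismatch, na.rm = TRUE)) {
        warning(sprintf("harmonize_pair: %d matched variant(s) have differing positions between '%s' and '%s'",
                        sum(mismatch, na.rm = TRUE), exposure_name, outcome_name),
                call. = FALSE)
      }
      out <- data.frame(
        variant_id = ek$variant_id,
        effect_allele = ek$effect_allele,
        other_allele = ek$other_allele,
        beta_exposure = ek$beta, se_exposure = ek$se,
        eaf_exposure = ek$eaf, pval_exposure = ek$pvalue,
        beta_outcome = beta_out, se_outcome = ok$se,
        eaf_outcome = eaf_out, pval_outcome = ok$pvalue,
        stringsAsFactors = FALSE
      )
      rownames(out) <- NULL
    }
  }

  if (n_kept == 0L) {
    stop(sprintf("harmonize_pair: zero harmonized instruments for exposure '%s' on outcome '%s'",
                 exposure_name, outcome_name))
  }

  log <- list(
    n_input = n_input, n_matched = n_kept, n_flipped = n_flipped,
    n_palindromic_removed = n_pal, n_incompatible_removed = n_incomp,
    n_unmatched = n_unmatched
  )
  structure(out,
            exposure = exposure_name, outcome = outcome_name, log = log,
            class = c("harmonized_instruments", "data.frame"))
}

#' Harmonization bookkeeping counts
#'
#' @param h A `harmonized_instruments` object.
#' @return The log: a list of counts (`n_input`, `n_matched`, `n_flipped`,
#'   `n_palindromic_removed`, `n_incompatible_removed`, `n_unmatched`).
#'   `n_matched + n_palindromic_removed + n_incompatible_removed +
#'   n_unmatched = n_input`.
#' @export
harmonization_log <- function(h) {
  stopifnot(inherits(h, "harmonized_instruments"))
  attr(h, "log")
}

#' @export
print.harmonized_instruments <- function(x, ...) {
  lg <- attr(x, "log")
  cat(sprintf("<harmonized_instruments> '%s' on '%s': %d kept (%d flipped) of %d; %d palindromic, %d incompatible, %d unmatched removed\n",
              attr(x, "exposure"), attr(x, "outcome"),
              lg$n_matched, lg$n_flipped, lg$n_input,
              lg$n_palindromic_removed, lg$n_incompatible_removed,
              lg$n_unmatched))
  print(head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more row(s)\n", nrow(x) - 6L))
  invisible(x)
}

#' Write harmonized instruments and their log
#'
#' Emits the harmonized table as tab-delimited text and, optionally, the
#' harmonization log as JSON.
#'
#' @param h A `harmonized_instruments` object.
#' @param path Output path for the table.
#' @param log_path Optional output path for the JSON log.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(h, path, log_path = NULL) {
  stopifnot(inherits(h, "harmonized_instruments"))
  utils::write.table(as.data.frame(h), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(log_path)) {
    jsonlite::write_json(harmonization_log(h), log_path, auto_unbox = TRUE)
  }
  invisible(path)
}
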