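#  Two-step MR mediator screening and the coefficient-difference
#  decomposition of a total causal effect into direct and mediated parts.

#' Delta-method standard error of a product of coefficients
#'
#' First-order standard error of `b1 * b2` for independently estimated
#' coefficients: `sqrt(b2^2 se1^2 + b1^2 se2^2)`.
#'
#' @param b1,se1 First coefficient and its standard error (`se1 > 0`).
#' @param b2,se2 Second coefficient and its standard error (`se2 > 0`).
#' @return The standard error of the product.
#' @export
#' @examples
#' indirect_se_delta(1, 0.1, 0, 0.2)  # 0.2
indirect_se_delta <- function(b1, se1, b2, se2) {
  stopifnot(se1 > 0, se2 > 0)
  sqrt(b2^2 * se1^2 + b1^2 * se2^2)
}

#' Delta-method standard error of the proportion mediated
#'
#' First-order standard error of `b1 * b2 / total` treating the three
#' estimates as independent (they come from separate regressions):
#' `sqrt((b2 se1 / total)^2 + (b1 se2 / total)^2 +
#' (b1 b2 se_total / total^2)^2)`.
#'
#' @param total,se_total Total effect and its standard error.
#' @param b1,se1 Exposure-to-mediator effect and standard error.
#' @param b2,se2 Mediator-to-outcome effect and standard error.
#' @return The standard error of the proportion mediated.
#' @export
proportion_se_delta <- function(total, se_total, b1, se1, b2, se2) {
  stopifnot(total != 0, se_total > 0, se1 > 0, se2 > 0)
  sqrt((b2 * se1 / total)^2 + (b1 * se2 / total)^2 +
         (b1 * b2 * se_total / total^2)^2)
}

#' Coefficient-difference mediation decomposition
#'
#' Decomposes a total causal effect into an indirect (mediated) component
#' `b1 * b2` — the product of the exposure-to-mediator and
#' mediator-to-outcome effects — and a direct component
#' `total - b1 * b2`, with proportion mediated `indirect / total`. The
#' identity `direct + indirect = total` holds exactly. When step effects
#' are unavailable the indirect effect can be supplied directly via
#' `indirect`. With standard errors supplied, delta-method uncertainties
#' for the indirect effect and the proportion are included.
#'
#' @param total Total effect of the exposure on the outcome (log-odds for a
#'   binary outcome).
#' @param b1 Exposure-to-mediator effect.
#' @param b2 Mediator-to-outcome effect.
#' @param indirect Indirect effect; defaults to `b1 * b2`.
#' @param se_total,se_b1,se_b2 Optional standard errors.
#' @param exposure,mediator,outcome Optional trait labels.
#' @return A `mediation_result` list with fields `total`, `b1`, `b2`,
#'   `indirect`, `direct`, `proportion`, `indirect_se`, `proportion_se`,
#'   `proportion_ci`. With `total = 0` the proportion is `NA` (flagged by a
#'   warning) while the other fields are still returned.
#' @export
#' @examples
#' decompose_effect(0.670, indirect = 0.049)$direct  # 0.621
decompose_effect <- function(total, b1 = NULL, b2 = NULL, indirect = NULL,
                             se_total = NULL, se_b1 = NULL, se_b2 = NULL,
                             exposure = NA_character_,
                             mediator = NA_character_,
                             outcome = NA_character_) {
  if (is.null(indirect)) {
    if (is.null(b1) || is.null(b2)) {
      stop("supply either `b1` and `b2`, or `indirect`")
    }
    indirect <- b1 * b2
  }
  direct <- total - indirect
  if (total == 0) {
    warning("total effect is zero: proportion mediated is undefined",
            call. = FALSE)
    proportion <- NA_real_
  } else {
    proportion <- indirect / total
  }
  have_step_se <- !is.null(b1) && !is.null(b2) &&
    !is.null(se_b1) && !is.null(se_b2)
  indirect_se <- if (have_step_se) indirect_se_delta(b1, se_b1, b2, se_b2) else NA_real_
  proportion_se <- if (have_step_se && !is.null(se_total) && total != 0) {
    proportion_se_delta(total, se_total, b1, se_b1, b2, se_b2)
  } else NA_real_
  proportion_ci <- if (is.finite(proportion_se)) {
    proportion + c(-1.96, 1.96) * proportion_se
  } else c(NA_real_, NA_real_)
  structure(list(
    exposure = exposure, mediator = mediator, outcome = outcome,
    total = total, b1 = if (is.null(b1)) NA_real_ else b1,
    b2 = if (is.null(b2)) NA_real_ else b2,
    indirect = indirect, direct = direct, proportion = proportion,
    indirect_se = indirect_se, proportion_se = proportion_se,
    proportion_ci = proportion_ci
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> %s -> %s -> %s\n",
              x$exposure, x$mediator, x$outcome))
  cat(sprintf("  total = %.4g, indirect = %.4g, direct = %.4g\n",
              x$total, x$indirect, x$direct))
  if (is.finite(x$proportion)) {
    cat(sprintf("  proportion mediated = %.4g (%.2f%%)\n",
                x$proportion, 100 * x$proportion))
  } else {
    cat("  proportion mediated undefined (total effect 0)\n")
  }
  invisible(x)
}

#' @export
as.data.frame.mediation_result <- function(x, ...) {
  data.frame(
    exposure = x$exposure, mediator = x$mediator, outcome = x$outcome,
    total_effect = x$total, indirect_effect = x$indirect,
    direct_effect = x$direct, proportion = x$proportion,
    proportion_pct = if (is.finite(x$proportion))
      sprintf("%.2f%%", 100 * x$proportion) else NA_character_,
    indirect_se = x$indirect_se, proportion_se = x$proportion_se,
    stringsAsFactors = FALSE
  )
}

#' Step 1 of two-step mediation: exposure effects on candidate mediators
#'
#' For each candidate mediator GWAS, harmonizes the exposure instruments
#' against it and estimates the exposure-to-mediator effect by IVW. A
#' mediator passes when its IVW p-value is below `alpha`. Mediators with no
#' harmonizable instruments yield a decision row with reason
#' `"no instruments"` rather than a failure.
#'
#' @param instruments `summary_dataset` of selected, clumped exposure
#'   instruments.
#' @param mediators Named list of mediator `summary_dataset`s.
#' @param alpha Screening significance level (default 0.05, unadjusted).
#' @param ivw_mode IVW flavour.
#' @param p_adjust Optional multiple-testing adjustment of the screening
#'   p-values (`"none"` default, or `"BH"` for Benjamini-Hochberg).
#' @return Data frame with one row per mediator: `mediator`, `n_snp`,
#'   `beta1`, `se1`, `p_step1`, `passed`, `reason`.
#' @export
screen_step1 <- function(instruments, mediators, alpha = 0.05,
                         ivw_mode = c("mre", "fixed"),
                         p_adjust = c("none", "BH")) {
  ivw_mode <- match.arg(ivw_mode)
  p_adjust <- match.arg(p_adjust)
  stopifnot(alpha > 0, alpha < 1, is.list(mediators))
  if (is.null(names(mediators)) || any(!nzchar(names(mediators)))) {
    stop("`mediators` must be a named list")
  }
  rows <- lapply(names(mediators), function(nm) {
    h <- tryCatch(harmonize_pair(instruments, mediators[[nm]]),
                  error = function(e) NULL)
    if (is.null(h) || nrow(h) < 1L) {
      return(data.frame(mediator = nm, n_snp = 0L, beta1 = NA_real_,
                        se1 = NA_real_, p_step1 = NA_real_, passed = FALSE,
                        reason = "no instruments", stringsAsFactors = FALSE))
    }
    est <- suppressMessages(mr_ivw(h, mode = ivw_mode))
    data.frame(mediator = nm, n_snp = est$n_snp, beta1 = est$beta,
               se1 = est$se, p_step1 = est$pvalue, passed = NA,
               reason = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  p_eff <- out$p_step1
  if (p_adjust == "BH") p_eff <- stats::p.adjust(p_eff, method = "BH")
  out$passed <- !is.na(p_eff) & p_eff < alpha
  rownames(out) <- NULL
  out
}

#' Step 2 of two-step mediation: mediator effects on the outcome
#'
#' For each mediator that passed step 1, selects that mediator's own
#' instruments from its GWAS (significance threshold `p_threshold`,
#' clumped), harmonizes them against the outcome, and estimates the
#' mediator-to-outcome effect by IVW. A mediator passes when its p-value is
#' below `alpha` and, with `exclude_unnamed = TRUE` (default), when its
#' name does not match `unnamed_pattern` — unidentified metabolites
#' (conventionally `X-`-prefixed) carry too little information to act on.
#' Among the passers, the one with the smallest step-2 p-value is marked
#' `selected`.
#'
#' @param step1 Output of [screen_step1()].
#' @param mediators Named list of mediator `summary_dataset`s (instrument
#'   source).
#' @param outcome Outcome `summary_dataset`.
#' @param alpha Screening significance level.
#' @param exclude_unnamed Exclude mediators matching `unnamed_pattern`.
#' @param unnamed_pattern Regular expression identifying unnamed mediators.
#' @param p_threshold Instrument-selection threshold within each mediator
#'   GWAS (default 1e-5).
#' @param ld,clump_window_bp,clump_r2 Clumping parameters, see
#'   [clump_instruments()].
#' @param ivw_mode IVW flavour.
#' @return Data frame with one row per step-1 passer: `mediator`, `n_snp`,
#'   `beta2`, `se2`, `p_step2`, `named`, `passed`, `selected`, `reason`.
#' @export
screen_step2 <- function(step1, mediators, outcome, alpha = 0.05,
                         exclude_unnamed = TRUE, unnamed_pattern = "^X-",
                         p_threshold = 1e-5, ld = NULL,
                         clump_window_bp = 1e7, clump_r2 = 0.001,
                         ivw_mode = c("mre", "fixed")) {
  ivw_mode <- match.arg(ivw_mode)
  stopifnot(is.data.frame(step1), "mediator" %in% names(step1))
  cand <- step1$mediator[step1$passed]
  rows <- lapply(cand, function(nm) {
    named <- !grepl(unnamed_pattern, nm)
    gwas <- mediators[[nm]]
    if (is.null(gwas)) {
      return(data.frame(mediator = nm, n_snp = 0L, beta2 = NA_real_,
                        se2 = NA_real_, p_step2 = NA_real_, named = named,
                        passed = FALSE, selected = FALSE,
                        reason = "no GWAS", stringsAsFactors = FALSE))
    }
    iv <- suppressWarnings(select_instruments(gwas, p_threshold))
    iv <- suppressMessages(clump_instruments(iv, ld = ld,
                                             window_bp = clump_window_bp,
                                             r2_max = clump_r2))
    h <- if (nrow(iv)) {
      tryCatch(harmonize_pair(iv, outcome), error = function(e) NULL)
    } else NULL
    if (is.null(h) || nrow(h) < 1L) {
      return(data.frame(mediator = nm, n_snp = 0L, beta2 = NA_real_,
                        se2 = NA_real_, p_step2 = NA_real_, named = named,
                        passed = FALSE, selected = FALSE,
                        reason = "no instruments", stringsAsFactors = FALSE))
    }
    est <- suppressMessages(mr_ivw(h, mode = ivw_mode))
    sig <- est$pvalue < alpha
    passed <- sig && (named || !exclude_unnamed)
    reason <- if (!sig) "not significant"
      else if (!passed) "unnamed" else "ok"
    data.frame(mediator = nm, n_snp = est$n_snp, beta2 = est$beta,
               se2 = est$se, p_step2 = est$pvalue, named = named,
               passed = passed, selected = FALSE, reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(mediator = character(), n_snp = integer(),
               beta2 = numeric(), se2 = numeric(), p_step2 = numeric(),
               named = logical(), passed = logical(), selected = logical(),
               reason = character(), stringsAsFactors = FALSE)
  }
  if (any(out$passed)) {
    idx <- which(out$passed)
    best <- idx[order(out$p_step2[idx], out$mediator[idx])][1L]
    out$selected[best] <- TRUE
  }
  rownames(out) <- NULL
  out
}
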