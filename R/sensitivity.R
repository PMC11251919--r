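#  Heterogeneity, pleiotropy and outlier diagnostics: Cochran's Q, the
#  MR-Egger intercept, leave-one-out analysis, and MR-PRESSO.

#' Cochran's Q heterogeneity test
#'
#' `Q = sum_j w_j (beta_j - beta_ivw)^2` over the per-variant Wald ratios
#' `beta_j`, with weights `w_j = 1/se(beta_j)^2 = gamma_j^2 / se_Gamma_j^2`,
#' referred to a chi-square distribution with `J - 1` degrees of freedom.
#' Large Q indicates the instruments disagree about the causal effect —
#' a symptom of heterogeneity or horizontal pleiotropy.
#'
#' @param insts Harmonized instruments (>= 2 rows).
#' @param beta_ivw Pooled estimate to measure deviations from; defaults to
#'   the fixed-effect IVW slope.
#' @return List with `q_stat`, `q_df`, `q_pvalue`, `beta_ivw`.
#' @export
cochran_q <- function(insts, beta_ivw = NULL) {
  d <- hi_fields(insts)
  j <- length(d$g)
  if (j < 2L) stop("Cochran's Q requires at least 2 instruments")
  ratios <- d$G / d$g
  w <- d$g^2 / d$sG^2
  if (is.null(beta_ivw)) beta_ivw <- sum(w * ratios) / sum(w)
  q <- sum(w * (ratios - beta_ivw)^2)
  list(q_stat = q, q_df = j - 1L,
       q_pvalue = pchisq(q, df = j - 1L, lower.tail = FALSE),
       beta_ivw = beta_ivw)
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates the IVW causal effect with each instrument removed in turn.
#' An estimate that shifts materially when one variant is left out flags
#' that variant as influential.
#'
#' @param insts Harmonized instruments (>= 3 rows).
#' @param mode IVW flavour, see [mr_ivw()].
#' @return Data frame with one row per left-out variant: `left_out_id`,
#'   `beta`, `se`, `pvalue`, `n_snp`.
#' @export
leave_one_out <- function(insts, mode = c("mre", "fixed")) {
  mode <- match.arg(mode)
  d <- hi_fields(insts)
  j <- length(d$g)
  if (j < 3L) stop("leave-one-out requires at least 3 instruments")
  rows <- lapply(seq_len(j), function(k) {
    est <- mr_ivw(insts[-k, , drop = FALSE], mode = mode)
    data.frame(left_out_id = d$id[k], beta = est$beta, se = est$se,
               pvalue = est$pvalue, n_snp = est$n_snp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Simulation-based detection of pleiotropic outlier instruments.
#' (1) Global test: the observed weighted residual sum of squares
#' `RSS = sum_j w_j (Gamma_j - beta_(-j) gamma_j)^2`, with `beta_(-j)` the
#' leave-one-out IVW slope and `w_j = 1/se_Gamma_j^2`, is compared with its
#' null distribution obtained by simulating
#' `Gamma_j* ~ Normal(beta_(-j) gamma_j, se_Gamma_j)` `n_sim` times
#' (leave-one-out slopes are recomputed within each simulated dataset).
#' (2) Outlier test: each variant's observed weighted squared residual gets
#' a simulated tail p-value, Bonferroni-adjusted across variants; adjusted
#' p below `outlier_alpha` flags an outlier. (3) Distortion test: when
#' outliers are flagged, the relative change of the IVW estimate after
#' their removal is compared with the changes produced by removing equally
#' many randomly chosen variants. Empirical p-values use the add-one
#' `(k + 1)/(n_sim + 1)` form.
#'
#' @param insts Harmonized instruments (>= 4 rows).
#' @param n_sim Number of simulations (>= 100; default 1000).
#' @param seed Optional seed (RNG state restored on exit).
#' @param outlier_alpha Significance level for the Bonferroni-adjusted
#'   outlier test (default 0.05).
#' @param mode IVW flavour used for the corrected estimate.
#' @return An `mr_presso` list: `global_rss`, `global_p`, `outlier_table`
#'   (per-variant raw and adjusted p), `outliers` (variant ids),
#'   `distortion_coefficient` and `distortion_p` (`NA` when no outliers),
#'   and `corrected` — the IVW estimate on the outlier-free set, identical
#'   to the full-set IVW when nothing is flagged.
#' @export
mr_presso <- function(insts, n_sim = 1000L, seed = NULL,
                      outlier_alpha = 0.05, mode = c("mre", "fixed")) {
  mode <- match.arg(mode)
  d <- hi_fields(insts)
  j <- length(d$g)
  if (j < 4L) stop("insufficient instruments: MR-PRESSO requires at least 4")
  if (n_sim < 100L) stop("`n_sim` must be >= 100")

  w <- 1 / d$sG^2
  sxy <- sum(w * d$g * d$G)
  sxx <- sum(w * d$g^2)
  b_loo <- (sxy - w * d$g * d$G) / (sxx - w * d$g^2)
  resid_obs <- d$G - b_loo * d$g
  contrib_obs <- w * resid_obs^2
  rss_obs <- sum(contrib_obs)

  sim <- with_seed(seed, {
    mu <- b_loo * d$g
    draws <- matrix(rnorm(j * n_sim, mean = mu, sd = d$sG), nrow = j)
    sxy_s <- colSums(w * d$g * draws)
    b_loo_s <- (matrix(sxy_s, j, n_sim, byrow = TRUE) - (w * d$g) * draws) /
      (sxx - w * d$g^2)
    contrib_s <- w * (draws - b_loo_s * d$g)^2
    list(rss = colSums(contrib_s),
         tail = rowSums(contrib_s >= contrib_obs))
  })
  global_p <- (sum(sim$rss >= rss_obs) + 1) / (n_sim + 1)
  p_raw <- (sim$tail + 1) / (n_sim + 1)
  p_adj <- pmin(1, p_raw * j)
  is_outlier <- p_adj < outlier_alpha
  outliers <- d$id[is_outlier]

  full <- mr_ivw(insts, mode = mode)
  if (!length(outliers)) {
    corrected <- full
    distortion <- NA_real_
    distortion_p <- NA_real_
  } else {
    keep <- !is_outlier
    corrected <- if (sum(keep) >= 2L) {
      mr_ivw(insts[keep, , drop = FALSE], mode = mode)
    } else {
      full
    }
    distortion <- (full$beta - corrected$beta) / abs(corrected$beta)
    n_out <- length(outliers)
    perm <- with_seed(derive_seed(seed, 1L) %||% NULL, {
      vapply(seq_len(n_sim), function(i) {
        drop_idx <- sample.int(j, n_out)
        b_perm <- (sxy - sum(w[drop_idx] * d$g[drop_idx] * d$G[drop_idx])) /
          (sxx - sum(w[drop_idx] * d$g[drop_idx]^2))
        (full$beta - b_perm) / abs(b_perm)
      }, numeric(1))
    })
    distortion_p <- (sum(abs(perm) >= abs(distortion)) + 1) / (n_sim + 1)
  }

  structure(list(
    global_rss = rss_obs, global_p = global_p,
    outlier_table = data.frame(variant_id = d$id, p_raw = p_raw,
                               p_adj = p_adj, outlier = is_outlier,
                               stringsAsFactors = FALSE),
    outliers = outliers,
    distortion_coefficient = distortion, distortion_p = distortion_p,
    corrected = corrected, n_sim = n_sim, outlier_alpha = outlier_alpha
  ), class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("<mr_presso> global RSS = %.4g, p = %.3g; %d outlier(s)%s\n",
              x$global_rss, x$global_p, length(x$outliers),
              if (length(x$outliers))
                paste0(" (", paste(x$outliers, collapse = ", "), ")")
              else ""))
  if (length(x$outliers)) {
    cat(sprintf("  distortion = %.3g, p = %.3g\n",
                x$distortion_coefficient, x$distortion_p))
  }
  cat("  corrected: ")
  print(x$corrected)
  invisible(x)
}

#' Full sensitivity report for one exposure-outcome pair
#'
#' Bundles Cochran's Q, the MR-Egger intercept (>= 3 instruments), the
#' leave-one-out table (>= 3) and MR-PRESSO (>= 4) into one object. An
#' Egger intercept p-value at or above `pleiotropy_alpha` is reported as
#' "no directional pleiotropy detected".
#'
#' @param insts Harmonized instruments (>= 2 rows).
#' @param n_sim,seed,outlier_alpha Passed to [mr_presso()].
#' @param mode IVW flavour for the leave-one-out and corrected estimates.
#' @param pleiotropy_alpha Threshold for calling the Egger intercept
#'   non-zero (default 0.05).
#' @return A `sensitivity_report` list.
#' @export
sensitivity_report <- function(insts, n_sim = 1000L, seed = NULL,
                               outlier_alpha = 0.05,
                               mode = c("mre", "fixed"),
                               pleiotropy_alpha = 0.05) {
  mode <- match.arg(mode)
  j <- nrow(insts)
  q <- cochran_q(insts)
  egger <- if (j >= 3L) mr_egger(insts) else NULL
  loo <- if (j >= 3L) leave_one_out(insts, mode = mode) else NULL
  presso <- if (j >= 4L) {
    mr_presso(insts, n_sim = n_sim, seed = seed,
              outlier_alpha = outlier_alpha, mode = mode)
  } else NULL
  structure(list(
    n_snp = j,
    q_stat = q$q_stat, q_df = q$q_df, q_pvalue = q$q_pvalue,
    egger_intercept = if (!is.null(egger)) egger$extra$intercept else NA_real_,
    egger_intercept_se = if (!is.null(egger)) egger$extra$intercept_se else NA_real_,
    egger_intercept_p = if (!is.null(egger)) egger$extra$intercept_p else NA_real_,
    pleiotropy_detected = if (!is.null(egger))
      egger$extra$intercept_p < pleiotropy_alpha else NA,
    loo_table = loo,
    presso_global_p = if (!is.null(presso)) presso$global_p else NA_real_,
    presso_outliers = if (!is.null(presso)) presso$outliers else character(),
    presso_distortion_p = if (!is.null(presso)) presso$distortion_p else NA_real_,
    presso_corrected = if (!is.null(presso)) presso$corrected else NULL
  ), class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> %d instruments\n", x$n_snp))
  cat(sprintf("  Cochran's Q = %.4g (df %d), p = %.3g\n",
              x$q_stat, x$q_df, x$q_pvalue))
  cat(sprintf("  Egger intercept = %.4g (se %.4g), p = %.3g\n",
              x$egger_intercept, x$egger_intercept_se, x$egger_intercept_p))
  cat(sprintf("  MR-PRESSO global p = %.3g, outliers: %s\n",
              x$presso_global_p,
              if (length(x$presso_outliers))
                paste(x$presso_outliers, collapse = ", ") else "none"))
  invisible(x)
}

#' Serialize a sensitivity report to JSON
#'
#' The leave-one-out table is included as an array of rows; it can
#' additionally be written as delimited text with `loo_path` (the data
#' behind leave-one-out plots).
#'
#' @param report A `sensitivity_report`.
#' @param path Optional JSON output path; when `NULL` the JSON string is
#'   returned.
#' @param loo_path Optional tab-delimited output path for the
#'   leave-one-out table.
#' @return The JSON string (invisibly when written to `path`).
#' @export
sensitivity_to_json <- function(report, path = NULL, loo_path = NULL) {
  stopifnot(inherits(report, "sensitivity_report"))
  payload <- unclass(report)
  payload$presso_corrected <- if (!is.null(report$presso_corrected)) {
    unclass(report$presso_corrected)[c("method", "beta", "se", "pvalue", "n_snp")]
  }
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           na = "null", null = "null", dataframe = "rows")
  if (!is.null(loo_path) && !is.null(report$loo_table)) {
    utils::write.table(report$loo_table, loo_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
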