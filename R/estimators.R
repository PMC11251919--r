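#  Causal estimators on harmonized instruments: the per-variant Wald ratio,
#  inverse-variance-weighted (fixed and multiplicative-random-effects),
#  MR-Egger, and the weighted-median estimator.

#  Extract the (gamma, sigma_gamma, Gamma, sigma_Gamma) quadruple from a
#  harmonized-instruments table (or any data frame with those columns).
hi_fields <- function(insts) {
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  if (!is.data.frame(insts) || !all(need %in% names(insts))) {
    stop("instruments must be a data frame with columns ",
         paste(need, collapse = ", "))
  }
  if (any(insts$se_exposure <= 0) || any(insts$se_outcome <= 0)) {
    stop("standard errors must be positive")
  }
  list(
    id = if ("variant_id" %in% names(insts)) as.character(insts$variant_id)
         else as.character(seq_len(nrow(insts))),
    g = insts$beta_exposure, sg = insts$se_exposure,
    G = insts$beta_outcome, sG = insts$se_outcome
  )
}

#  Assemble an MR estimate; p two-sided normal, or t with `df` when given.
new_mr_estimate <- function(method, beta, se, n_snp, extra = list(),
                            df = NULL) {
  z <- beta / se
  pvalue <- if (is.null(df)) 2 * pnorm(-abs(z)) else 2 * pt(-abs(z), df = df)
  structure(list(
    method = method, beta = beta, se = se, pvalue = pvalue,
    or = exp(beta), ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se), n_snp = n_snp, extra = extra
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s (%d SNP%s): beta = %.4g (se %.4g), p = %.3g; OR %.3g [%.3g, %.3g]\n",
              x$method, x$n_snp, if (x$n_snp == 1) "" else "s",
              x$beta, x$se, x$pvalue, x$or, x$ci_low, x$ci_high))
  if (!is.null(x$extra$intercept)) {
    cat(sprintf("  intercept = %.4g (se %.4g), p = %.3g\n",
                x$extra$intercept, x$extra$intercept_se, x$extra$intercept_p))
  }
  invisible(x)
}

#' Wald ratio for a single instrument
#'
#' The per-variant causal estimate `Gamma / gamma` with first-order
#' (delta-method) standard error `se_Gamma / |gamma|`.
#'
#' @param inst One row of harmonized instruments.
#' @return An `mr_estimate` with `method = "wald_ratio"`.
#' @export
mr_wald_ratio <- function(inst) {
  d <- hi_fields(inst)
  if (length(d$g) != 1L) stop("`mr_wald_ratio` takes exactly one instrument")
  if (d$g == 0) stop("domain error: exposure effect gamma is zero")
  new_mr_estimate("wald_ratio", beta = d$G / d$g, se = d$sG / abs(d$g),
                  n_snp = 1L)
}

#  Core IVW slope pieces shared with the sensitivity module.
ivw_core <- function(g, sg, G, sG) {
  w <- 1 / sG^2
  sxx <- sum(w * g^2)
  beta <- sum(w * g * G) / sxx
  ratios <- G / g
  w_ratio <- g^2 / sG^2
  q <- sum(w_ratio * (ratios - beta)^2)
  list(beta = beta, se_fixed = 1 / sqrt(sxx), q = q)
}

#' Inverse-variance-weighted causal estimate
#'
#' Weighted regression of the outcome effects on the exposure effects
#' through the origin with weights `1/se_outcome^2` — equivalently the
#' inverse-variance-weighted mean of the per-variant Wald ratios. The
#' default multiplicative random-effects model (`mode = "mre"`, the
#' behaviour of the standard two-sample-MR tooling) inflates the
#' fixed-effect standard error by `max(1, sqrt(Q / (J - 1)))` where `Q` is
#' Cochran's heterogeneity statistic of the ratio estimates; `mode =
#' "fixed"` reports the uninflated standard error. P-values are two-sided
#' normal. A single instrument degrades to the Wald ratio with a message.
#'
#' @param insts Harmonized instruments (>= 1 row).
#' @param mode `"mre"` (default) or `"fixed"`.
#' @return An `mr_estimate`; `extra` carries `q_stat`, `q_df`, `q_pvalue`
#'   and the applied inflation `scale`.
#' @export
mr_ivw <- function(insts, mode = c("mre", "fixed")) {
  mode <- match.arg(mode)
  d <- hi_fields(insts)
  j <- length(d$g)
  if (j == 0L) stop("no instruments supplied")
  if (j == 1L) {
    message("mr_ivw: single instrument; returning the Wald ratio")
    return(mr_wald_ratio(insts))
  }
  core <- ivw_core(d$g, d$sg, d$G, d$sG)
  scale <- if (mode == "mre") max(1, sqrt(core$q / (j - 1))) else 1
  new_mr_estimate("ivw", beta = core$beta, se = core$se_fixed * scale,
                  n_snp = j,
                  extra = list(mode = mode, q_stat = core$q, q_df = j - 1L,
                               q_pvalue = pchisq(core$q, j - 1L,
                                                 lower.tail = FALSE),
                               scale = scale))
}

#' MR-Egger regression
#'
#' Weighted regression `Gamma = alpha + beta * gamma` with weights
#' `1/se_outcome^2`, after orienting all exposure effects non-negative
#' (jointly flipping the sign of `gamma` and `Gamma` where `gamma < 0`, to
#' which the estimator is invariant). The slope is the causal estimate; a
#' non-zero intercept `alpha` indicates average directional horizontal
#' pleiotropy. Standard errors use multiplicative residual inflation
#' floored at 1, and p-values use the t distribution with `J - 2` degrees
#' of freedom.
#'
#' @param insts Harmonized instruments (>= 3 rows).
#' @return An `mr_estimate` with `method = "egger"`; `extra` carries
#'   `intercept`, `intercept_se`, `intercept_p` and the residual scale
#'   `sigma`.
#' @export
mr_egger <- function(insts) {
  d <- hi_fields(insts)
  j <- length(d$g)
  if (j < 3L) stop("insufficient instruments: MR-Egger requires at least 3")
  s <- sign(d$g)
  s[s == 0] <- 1
  x <- d$g * s
  y <- d$G * s
  fit <- summary(lm(y ~ x, weights = 1 / d$sG^2))
  est <- fit$coefficients
  infl <- 1 / min(1, fit$sigma)  # floor multiplicative inflation at 1
  slope <- est["x", "Estimate"]
  slope_se <- est["x", "Std. Error"] * infl
  intercept <- est["(Intercept)", "Estimate"]
  intercept_se <- est["(Intercept)", "Std. Error"] * infl
  new_mr_estimate("egger", beta = slope, se = slope_se, n_snp = j,
                  df = j - 2L,
                  extra = list(
                    intercept = intercept, intercept_se = intercept_se,
                    intercept_p = 2 * pt(-abs(intercept / intercept_se),
                                         df = j - 2L),
                    sigma = fit$sigma))
}

#  Weighted median of values `b` with weights `w`: linear interpolation of
#  the sorted values at standardized cumulative weight 0.5.
weighted_median_point <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o]
  s <- (cumsum(w) - 0.5 * w) / sum(w)
  if (s[1] >= 0.5) return(b[1])
  n <- length(b)
  if (s[n] <= 0.5) return(b[n])
  below <- max(which(s < 0.5))
  b[below] + (b[below + 1] - b[below]) * (0.5 - s[below]) / (s[below + 1] - s[below])
}

#' Weighted-median causal estimate
#'
#' Orders the per-variant Wald ratios and takes the value at the 50% point
#' of the standardized cumulative inverse-variance weights
#' `S_j = (sum_{i<=j} w_i - w_j/2) / sum(w)` by linear interpolation. The
#' estimate is consistent when at least half the total weight comes from
#' valid instruments, making it robust to a minority of pleiotropic
#' variants. The standard error is obtained by parametric bootstrap:
#' each ratio is resampled from `Normal(ratio_j, se_j)` and the weighted
#' median recomputed.
#'
#' @param insts Harmonized instruments (>= 3 rows).
#' @param n_boot Bootstrap replicates (>= 100; default 1000).
#' @param seed Optional seed for the bootstrap (restores RNG state).
#' @return An `mr_estimate` with `method = "weighted_median"`.
#' @export
mr_weighted_median <- function(insts, n_boot = 1000L, seed = NULL) {
  d <- hi_fields(insts)
  j <- length(d$g)
  if (j < 3L) stop("insufficient instruments: weighted median requires at least 3")
  if (n_boot < 100L) stop("`n_boot` must be >= 100")
  ratios <- d$G / d$g
  ses <- d$sG / abs(d$g)
  w <- 1 / ses^2
  est <- weighted_median_point(ratios, w)
  boots <- with_seed(seed, {
    draws <- matrix(rnorm(j * n_boot, mean = ratios, sd = ses), nrow = j)
    apply(draws, 2L, weighted_median_point, w = w)
  })
  new_mr_estimate("weighted_median", beta = est, se = sd(boots), n_snp = j,
                  extra = list(n_boot = n_boot))
}

#' Run all three estimators on one instrument set
#'
#' @param insts Harmonized instruments.
#' @param ivw_mode IVW flavour, see [mr_ivw()].
#' @param n_boot,seed Passed to [mr_weighted_median()].
#' @return Named list of `mr_estimate`s (`ivw`, plus `egger` and
#'   `weighted_median` when at least 3 instruments are available).
#' @export
mr_all <- function(insts, ivw_mode = c("mre", "fixed"), n_boot = 1000L,
                   seed = NULL) {
  ivw_mode <- match.arg(ivw_mode)
  out <- list(ivw = mr_ivw(insts, mode = ivw_mode))
  if (nrow(insts) >= 3L) {
    out$egger <- mr_egger(insts)
    out$weighted_median <- mr_weighted_median(insts, n_boot = n_boot,
                                              seed = seed)
  }
  out
}

#' Bind MR estimates into a conventional results table
#'
#' One row per method with the column layout used by standard
#' two-sample-MR tooling: `exposure`, `outcome`, `method`, `nsnp`, `b`,
#' `se`, `pval`, `or`, `or_lci95`, `or_uci95`.
#'
#' @param estimates A single `mr_estimate` or a list of them.
#' @param exposure,outcome Trait labels for the table.
#' @return A data frame.
#' @export
mr_results_table <- function(estimates, exposure = "exposure",
                             outcome = "outcome") {
  if (inherits(estimates, "mr_estimate")) estimates <- list(estimates)
  rows <- lapply(estimates, function(e) {
    data.frame(exposure = exposure, outcome = outcome, method = e$method,
               nsnp = e$n_snp, b = e$beta, se = e$se, pval = e$pvalue,
               or = e$or, or_lci95 = e$ci_low, or_uci95 = e$ci_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
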