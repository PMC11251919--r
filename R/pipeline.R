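#  Batch orchestration: forward MR across many exposures, reverse MR, and
#  two-step mediation, with structured logging and deterministic seeding.

#' Analysis configuration
#'
#' Collects every threshold and estimator setting used by the batch
#' drivers. Defaults: instruments at p < 1e-5 for exposures and mediators
#' (the relaxed threshold used when genome-wide hits are scarce), p < 5e-5
#' for reverse analyses, 10 Mb / r-squared 0.001 clumping, F > 10 for
#' instrument strength, significance at 0.05 with no multiple-testing
#' adjustment (an optional Benjamini-Hochberg column can be added by the
#' drivers), multiplicative-random-effects IVW, 1000 bootstrap and
#' MR-PRESSO draws, unnamed mediators (names matching `^X-`) excluded.
#'
#' @param p_threshold_exposure,p_threshold_mediator,p_threshold_reverse,p_threshold_gwas
#'   Instrument-selection thresholds.
#' @param clump_window_bp,clump_r2 Clumping parameters.
#' @param f_min Minimum acceptable F statistic.
#' @param alpha Significance level for causal calls and screening.
#' @param ivw_mode `"mre"` or `"fixed"`.
#' @param n_boot Weighted-median bootstrap replicates.
#' @param presso_n_sim MR-PRESSO simulation count.
#' @param outlier_alpha MR-PRESSO outlier significance level.
#' @param exclude_unnamed,unnamed_pattern Unnamed-mediator handling.
#' @param run_sensitivity Compute sensitivity reports in [run_forward()].
#' @param fdr Add Benjamini-Hochberg adjusted p-value columns (reported
#'   alongside, never changing the significant set).
#' @param seed Base seed; every stochastic step derives its own seed from
#'   it, making batch runs reproducible.
#' @return An `mr_config` list.
#' @export
mr_config <- function(p_threshold_exposure = 1e-5,
                      p_threshold_mediator = 1e-5,
                      p_threshold_reverse = 5e-5,
                      p_threshold_gwas = 5e-8,
                      clump_window_bp = 1e7, clump_r2 = 0.001,
                      f_min = 10, alpha = 0.05,
                      ivw_mode = c("mre", "fixed"),
                      n_boot = 1000L, presso_n_sim = 1000L,
                      outlier_alpha = 0.05,
                      exclude_unnamed = TRUE, unnamed_pattern = "^X-",
                      run_sensitivity = TRUE, fdr = FALSE, seed = 1L) {
  ivw_mode <- match.arg(ivw_mode)
  for (p in c(p_threshold_exposure, p_threshold_mediator,
              p_threshold_reverse, p_threshold_gwas, alpha, outlier_alpha)) {
    stopifnot(is.numeric(p), p > 0, p < 1)
  }
  stopifnot(clump_window_bp > 0, clump_r2 >= 0, clump_r2 < 1,
            n_boot >= 100, presso_n_sim >= 100)
  structure(list(
    p_threshold_exposure = p_threshold_exposure,
    p_threshold_mediator = p_threshold_mediator,
    p_threshold_reverse = p_threshold_reverse,
    p_threshold_gwas = p_threshold_gwas,
    clump_window_bp = clump_window_bp, clump_r2 = clump_r2,
    f_min = f_min, alpha = alpha, ivw_mode = ivw_mode,
    n_boot = as.integer(n_boot), presso_n_sim = as.integer(presso_n_sim),
    outlier_alpha = outlier_alpha,
    exclude_unnamed = exclude_unnamed, unnamed_pattern = unnamed_pattern,
    run_sensitivity = run_sensitivity, fdr = fdr, seed = as.integer(seed)
  ), class = "mr_config")
}

#' Taxon registry
#'
#' A table of microbial taxa with their taxonomic rank and whether the
#' taxon has a specific name; unnamed ("unknown") taxa are excluded from
#' analysis by [filter_taxa()].
#'
#' @param name Character vector of taxon names.
#' @param rank Taxonomic ranks, each one of `class`, `family`, `genus`,
#'   `order`, `phylum`.
#' @param known Logical: does the taxon have a specific name?
#' @return A `taxon_registry` data frame.
#' @export
taxon_registry <- function(name, rank, known = TRUE) {
  ranks <- c("class", "family", "genus", "order", "phylum")
  rank <- as.character(rank)
  if (!all(rank %in% ranks)) {
    stop("`rank` entries must be one of: ", paste(ranks, collapse = ", "))
  }
  out <- data.frame(name = as.character(name), rank = rank,
                    known = rep_len(as.logical(known), length(name)),
                    stringsAsFactors = FALSE)
  structure(out, class = c("taxon_registry", "data.frame"))
}

#' Remove unknown taxa from a registry
#'
#' Drops taxa flagged as unknown (no specific name) and logs the retained
#' counts by rank.
#'
#' @param reg A [taxon_registry()].
#' @return The filtered `taxon_registry`.
#' @export
filter_taxa <- function(reg) {
  stopifnot(inherits(reg, "taxon_registry"))
  out <- reg[reg$known, , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out)) {
    warning("all taxa are unknown; registry is empty after filtering",
            call. = FALSE)
  } else {
    counts <- table(out$rank)
    message(sprintf("filter_taxa: retained %d of %d taxa (%s)",
                    nrow(out), nrow(reg),
                    paste(sprintf("%d %s", counts, names(counts)),
                          collapse = ", ")))
  }
  structure(out, class = c("taxon_registry", "data.frame"))
}

#  Shared instrument preparation: select, clump, optional F check.
prepare_instruments <- function(ds, p_threshold, config, ld = NULL) {
  iv <- suppressWarnings(select_instruments(ds, p_threshold))
  if (!nrow(iv)) return(list(iv = iv, reason = "no instruments at threshold"))
  iv <- suppressMessages(clump_instruments(iv, ld = ld,
                                           window_bp = config$clump_window_bp,
                                           r2_max = config$clump_r2))
  if (nrow(iv) < 2L) return(list(iv = iv, reason = "fewer than 2 independent instruments"))
  list(iv = iv, reason = NULL)
}

#  Do the slopes of the available estimators agree in sign with IVW?
direction_consistent <- function(ests) {
  signs <- vapply(ests, function(e) sign(e$beta), numeric(1))
  all(signs == signs[["ivw"]])
}

#' Forward MR of many exposures on one outcome
#'
#' For each exposure: select instruments at the exposure threshold, clump,
#' harmonize against the outcome, run IVW, MR-Egger and weighted-median
#' estimators, and (optionally) the full sensitivity suite. Exposures that
#' cannot be analysed (no instruments, nothing harmonizable) are recorded
#' in the skip log and never abort the batch; every input exposure appears
#' either in the results or in the skip log.
#'
#' @param exposures Named list of exposure `summary_dataset`s.
#' @param outcome Outcome `summary_dataset`.
#' @param config An [mr_config()].
#' @param ld Optional LD matrix for clumping.
#' @return An `mr_forward` list: `results` (one row per exposure and
#'   method), `summary` (one row per analysed exposure with the IVW call,
#'   instrument strength and direction-consistency flag), `sensitivity`
#'   (named list of [sensitivity_report()]s), `skipped`, `significant`
#'   (exposure names with IVW p < alpha), `config`.
#' @export
run_forward <- function(exposures, outcome, config = mr_config(), ld = NULL) {
  stopifnot(inherits(config, "mr_config"), is.list(exposures))
  if (length(exposures) && (is.null(names(exposures)) ||
                            any(!nzchar(names(exposures))))) {
    stop("`exposures` must be a named list")
  }
  results <- list()
  summaries <- list()
  sens <- list()
  skipped <- list()
  for (i in seq_along(exposures)) {
    nm <- names(exposures)[i]
    prep <- prepare_instruments(exposures[[i]], config$p_threshold_exposure,
                                config, ld)
    if (!is.null(prep$reason)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(exposure = nm, reason = prep$reason,
                   stringsAsFactors = FALSE)
      next
    }
    h <- tryCatch(harmonize_pair(prep$iv, outcome), error = function(e) NULL)
    if (is.null(h) || nrow(h) < 2L) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(exposure = nm,
                   reason = "fewer than 2 harmonized instruments",
                   stringsAsFactors = FALSE)
      next
    }
    ests <- suppressMessages(
      mr_all(h, ivw_mode = config$ivw_mode, n_boot = config$n_boot,
             seed = derive_seed(config$seed, i))
    )
    results[[length(results) + 1L]] <-
      mr_results_table(ests, exposure = nm,
                       outcome = attr(outcome, "trait_name"))
    f <- if (all(is.finite(h$eaf_exposure))) {
      tryCatch(f_statistic(sum(2 * h$eaf_exposure * (1 - h$eaf_exposure) *
                                 h$beta_exposure^2),
                           n = attr(exposures[[i]], "n_total"),
                           k = nrow(h))$f_stat,
               error = function(e) NA_real_)
    } else NA_real_
    ivw <- ests$ivw
    summaries[[length(summaries) + 1L]] <- data.frame(
      exposure = nm, nsnp = ivw$n_snp, f_stat = f,
      b_ivw = ivw$beta, se_ivw = ivw$se, p_ivw = ivw$pvalue,
      significant = ivw$pvalue < config$alpha,
      direction_consistent = direction_consistent(ests),
      stringsAsFactors = FALSE
    )
    if (config$run_sensitivity && nrow(h) >= 2L) {
      sens[[nm]] <- sensitivity_report(h, n_sim = config$presso_n_sim,
                                       seed = derive_seed(config$seed, 10000 + i),
                                       outlier_alpha = config$outlier_alpha,
                                       mode = config$ivw_mode)
    }
  }
  results <- if (length(results)) do.call(rbind, results) else NULL
  summary <- if (length(summaries)) do.call(rbind, summaries) else NULL
  if (!is.null(summary) && config$fdr) {
    summary$p_ivw_fdr <- stats::p.adjust(summary$p_ivw, method = "BH")
  }
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(exposure = character(), reason = character(),
               stringsAsFactors = FALSE)
  if (!length(exposures)) {
    warning("run_forward: empty exposure collection", call. = FALSE)
  }
  structure(list(
    results = results, summary = summary, sensitivity = sens,
    skipped = skipped,
    significant = if (!is.null(summary))
      summary$exposure[summary$significant] else character(),
    config = config
  ), class = "mr_forward")
}

#' Reverse MR: the outcome as exposure
#'
#' Selects instruments for the outcome at the (more permissive) reverse
#' threshold, clumps them, and estimates the outcome's effect on each
#' candidate trait by IVW. A reverse p-value below `alpha` flags possible
#' reverse causation for that trait.
#'
#' @param outcome Outcome `summary_dataset`, now treated as the exposure.
#' @param exposures Named list of trait `summary_dataset`s, now treated as
#'   outcomes.
#' @param config An [mr_config()].
#' @param ld Optional LD matrix.
#' @return List with `results` (one row per trait: `b`, `se`, `pval`,
#'   `reverse_flag`) and `skipped`.
#' @export
run_reverse <- function(outcome, exposures, config = mr_config(), ld = NULL) {
  stopifnot(inherits(config, "mr_config"))
  prep <- prepare_instruments(outcome, config$p_threshold_reverse, config, ld)
  if (!is.null(prep$reason)) {
    return(list(results = NULL,
                skipped = data.frame(trait = names(exposures),
                                     reason = paste("outcome:", prep$reason),
                                     stringsAsFactors = FALSE)))
  }
  rows <- list()
  skipped <- list()
  for (nm in names(exposures)) {
    h <- tryCatch(harmonize_pair(prep$iv, exposures[[nm]]),
                  error = function(e) NULL)
    if (is.null(h) || nrow(h) < 2L) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(trait = nm, reason = "fewer than 2 harmonized instruments",
                   stringsAsFactors = FALSE)
      next
    }
    est <- suppressMessages(mr_ivw(h, mode = config$ivw_mode))
    rows[[length(rows) + 1L]] <- data.frame(
      exposure = attr(outcome, "trait_name"), outcome = nm,
      nsnp = est$n_snp, b = est$beta, se = est$se, pval = est$pvalue,
      reverse_flag = est$pvalue < config$alpha, stringsAsFactors = FALSE
    )
  }
  list(
    results = if (length(rows)) do.call(rbind, rows) else NULL,
    skipped = if (length(skipped)) do.call(rbind, skipped) else
      data.frame(trait = character(), reason = character(),
                 stringsAsFactors = FALSE)
  )
}

#' Two-step mediation across the significant exposures
#'
#' For each exposure flagged significant by [run_forward()]: screen the
#' candidate mediators (exposure-to-mediator IVW, then
#' mediator-to-outcome IVW with the unnamed-mediator exclusion and
#' smallest-p selection rule) and decompose the exposure's total effect
#' into mediated and direct components via the selected mediator. An
#' exposure with no surviving mediator is reported with empty mediator
#' fields.
#'
#' @param forward An `mr_forward` result.
#' @param exposures Named list of exposure `summary_dataset`s (instrument
#'   source; must cover the significant exposures).
#' @param mediators Named list of candidate mediator `summary_dataset`s.
#' @param outcome Outcome `summary_dataset`.
#' @param config An [mr_config()].
#' @param ld Optional LD matrix.
#' @return List with `table` (one row per significant exposure, Table-1
#'   layout: total, indirect, direct effects and proportion mediated),
#'   `step1` and `step2` (per-exposure screening decision tables).
#' @export
run_mediation <- function(forward, exposures, mediators, outcome,
                          config = mr_config(), ld = NULL) {
  stopifnot(inherits(forward, "mr_forward"), inherits(config, "mr_config"))
  sig <- forward$significant
  rows <- list()
  step1_all <- list()
  step2_all <- list()
  for (nm in sig) {
    prep <- prepare_instruments(exposures[[nm]], config$p_threshold_exposure,
                                config, ld)
    if (!is.null(prep$reason)) next
    s1 <- screen_step1(prep$iv, mediators, alpha = config$alpha,
                       ivw_mode = config$ivw_mode)
    s2 <- screen_step2(s1, mediators, outcome, alpha = config$alpha,
                       exclude_unnamed = config$exclude_unnamed,
                       unnamed_pattern = config$unnamed_pattern,
                       p_threshold = config$p_threshold_mediator, ld = ld,
                       clump_window_bp = config$clump_window_bp,
                       clump_r2 = config$clump_r2,
                       ivw_mode = config$ivw_mode)
    step1_all[[nm]] <- s1
    step2_all[[nm]] <- s2
    tot <- forward$summary[forward$summary$exposure == nm, ]
    if (any(s2$selected)) {
      sel <- s2[s2$selected, ]
      b1row <- s1[s1$mediator == sel$mediator, ]
      res <- decompose_effect(
        total = tot$b_ivw, b1 = b1row$beta1, b2 = sel$beta2,
        se_total = tot$se_ivw, se_b1 = b1row$se1, se_b2 = sel$se2,
        exposure = nm, mediator = sel$mediator,
        outcome = attr(outcome, "trait_name")
      )
      rows[[length(rows) + 1L]] <- as.data.frame(res)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        exposure = nm, mediator = NA_character_,
        outcome = attr(outcome, "trait_name"),
        total_effect = tot$b_ivw, indirect_effect = NA_real_,
        direct_effect = NA_real_, proportion = NA_real_,
        proportion_pct = NA_character_, indirect_se = NA_real_,
        proportion_se = NA_real_, stringsAsFactors = FALSE
      )
    }
  }
  list(
    table = if (length(rows)) do.call(rbind, rows) else NULL,
    step1 = step1_all, step2 = step2_all
  )
}
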