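#  Seeded generator of GWAS summary statistics with a known
#  exposure -> mediator -> outcome causal chain, for validating every stage
#  of the pipeline without individual-level or consortium data.

#' Pleiotropy specifications for the chain simulator
#'
#' Describe how exposure instruments violate the exclusion restriction:
#' `pleiotropy_none()` — valid instruments; `pleiotropy_balanced(sd)` —
#' zero-mean direct outcome effects; `pleiotropy_directional(mean, sd)` —
#' direct effects with a common offset (detectable by the Egger
#' intercept); `pleiotropy_outlier(k, shift)` — `k` instruments get their
#' outcome effect shifted by `shift` outcome standard errors (detectable
#' by MR-PRESSO).
#'
#' @param sd Standard deviation of per-variant direct outcome effects.
#' @param mean Mean direct outcome effect (directional pleiotropy).
#' @param k Number of outlier instruments.
#' @param shift Outlier shift in units of the outcome standard error.
#' @return A pleiotropy specification list.
#' @export
pleiotropy_none <- function() list(type = "none")

#' @rdname pleiotropy_none
#' @export
pleiotropy_balanced <- function(sd) {
  stopifnot(sd >= 0)
  list(type = "balanced", sd = sd)
}

#' @rdname pleiotropy_none
#' @export
pleiotropy_directional <- function(mean, sd = 0) {
  stopifnot(sd >= 0)
  list(type = "directional", mean = mean, sd = sd)
}

#' @rdname pleiotropy_none
#' @export
pleiotropy_outlier <- function(k, shift) {
  stopifnot(k >= 0, is.finite(shift))
  list(type = "outlier", k = as.integer(k), shift = shift)
}

#' Scenario for the exposure-mediator-outcome chain simulator
#'
#' Defines the causal structure and GWAS regimes emulated by
#' [simulate_chain()] and [simulate_mediation_study()]. Defaults mirror the
#' study setting the package was validated against: a microbiome-scale
#' exposure GWAS (n = 18,340), a metabolite-scale mediator GWAS
#' (n = 8,299), and a severely case/control-imbalanced binary outcome
#' (243 cases vs 287,137 controls) whose log-odds standard errors are
#' scaled by the effective sample size `4 / (1/cases + 1/controls)`.
#'
#' @param n_instruments_exposure,n_instruments_mediator,n_instruments_outcome
#'   Number of genuinely associated variants per trait (outcome
#'   instruments, default 0, support reverse-direction analyses).
#' @param beta1 Exposure-to-mediator causal effect.
#' @param beta2 Mediator-to-outcome causal effect.
#' @param direct Direct exposure-to-outcome effect (not through the
#'   mediator). The implied total effect is `beta1 * beta2 + direct`.
#' @param pleiotropy A specification from [pleiotropy_none()] and friends,
#'   applied to the exposure instruments' outcome effects.
#' @param gamma_range_exposure,gamma_range_mediator,gamma_range_outcome
#'   Ranges of per-variant true effect magnitudes (signs random).
#' @param n_exp,n_med GWAS sample sizes for exposure and mediator.
#' @param n_out_cases,n_out_controls Outcome case/control counts.
#' @param maf_range Range of minor-allele frequencies.
#' @param frac_palindromic Fraction of variants given palindromic (A/T or
#'   C/G) allele pairs.
#' @param ld_blocks Optional list `list(n_blocks, size, r2)`: the first
#'   `n_blocks` exposure instruments are expanded into blocks of `size`
#'   correlated variants (pairwise r-squared `r2`, 1 kb apart); the LD
#'   matrix is attached to the exposure dataset as attribute `"ld"`.
#' @param seed Integer seed; simulation is deterministic given the seed.
#' @return A `chain_scenario` list, including the implied `true_total`,
#'   `true_indirect`, `true_direct`, `true_proportion`.
#' @export
chain_scenario <- function(n_instruments_exposure = 50L,
                           n_instruments_mediator = 50L,
                           n_instruments_outcome = 0L,
                           beta1 = 0.3, beta2 = 0.5, direct = 0.2,
                           pleiotropy = pleiotropy_none(),
                           gamma_range_exposure = c(0.10, 0.20),
                           gamma_range_mediator = c(0.15, 0.30),
                           gamma_range_outcome = c(0.30, 0.60),
                           n_exp = 18340L, n_med = 8299L,
                           n_out_cases = 243L, n_out_controls = 287137L,
                           maf_range = c(0.10, 0.50),
                           frac_palindromic = 0.10,
                           ld_blocks = NULL, seed = 1L) {
  stopifnot(n_instruments_exposure >= 1, n_instruments_mediator >= 0,
            n_instruments_outcome >= 0,
            n_exp > 0, n_med > 0, n_out_cases > 0, n_out_controls > 0,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            frac_palindromic >= 0, frac_palindromic <= 1)
  true_indirect <- beta1 * beta2
  true_total <- true_indirect + direct
  structure(list(
    n_instruments_exposure = as.integer(n_instruments_exposure),
    n_instruments_mediator = as.integer(n_instruments_mediator),
    n_instruments_outcome = as.integer(n_instruments_outcome),
    beta1 = beta1, beta2 = beta2, direct = direct,
    pleiotropy = pleiotropy,
    gamma_range_exposure = gamma_range_exposure,
    gamma_range_mediator = gamma_range_mediator,
    gamma_range_outcome = gamma_range_outcome,
    n_exp = as.integer(n_exp), n_med = as.integer(n_med),
    n_out_cases = as.integer(n_out_cases),
    n_out_controls = as.integer(n_out_controls),
    n_out_eff = 4 / (1 / n_out_cases + 1 / n_out_controls),
    maf_range = maf_range, frac_palindromic = frac_palindromic,
    ld_blocks = ld_blocks, seed = as.integer(seed),
    true_total = true_total, true_indirect = true_indirect,
    true_direct = direct,
    true_proportion = if (true_total != 0) true_indirect / true_total else NA_real_
  ), class = "chain_scenario")
}

#  GWAS standard error of a per-allele effect on a unit-variance trait.
se_gwas <- function(maf, n) 1 / sqrt(2 * maf * (1 - maf) * n)

#  Genomic layout: slot i goes to chromosome ((i-1) %% 22) + 1 at position
#  1e6 + 2.5e7 * ((i-1) %/% 22), so distinct slots are always farther apart
#  than the default 10 Mb clumping window.
snp_layout <- function(idx) {
  list(chromosome = as.character(((idx - 1L) %% 22L) + 1L),
       position = 1e6 + 2.5e7 * ((idx - 1L) %/% 22L))
}

#  Random allele pairs with a given palindromic fraction.
draw_alleles <- function(n, frac_palindromic) {
  pal_pairs <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  nonpal <- list(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                 c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
  is_pal <- runif(n) < frac_palindromic
  pick <- function(pool, k) pool[sample.int(length(pool), k, replace = TRUE)]
  out <- vector("list", n)
  out[is_pal] <- pick(pal_pairs, sum(is_pal))
  out[!is_pal] <- pick(nonpal, sum(!is_pal))
  list(effect = vapply(out, `[`, character(1), 1L),
       other = vapply(out, `[`, character(1), 2L),
       is_pal = is_pal)
}

#  Emit one GWAS summary dataset from true per-variant effects, with a
#  fraction of rows reported in the opposite allele orientation (as real
#  consortia do) to exercise harmonization.
emit_gwas <- function(snps, mu, ses, trait_name, trait_type, n_total,
                      scramble = 0.3) {
  beta_hat <- rnorm(length(mu), mean = mu, sd = ses)
  p <- pmax(2 * pnorm(-abs(beta_hat / ses)), 1e-300)
  flip <- runif(length(mu)) < scramble
  rec <- data.frame(
    variant_id = snps$variant_id,
    chromosome = snps$chromosome,
    position = snps$position,
    effect_allele = ifelse(flip, snps$other_allele, snps$effect_allele),
    other_allele = ifelse(flip, snps$effect_allele, snps$other_allele),
    eaf = ifelse(flip, 1 - snps$maf, snps$maf),
    beta = ifelse(flip, -beta_hat, beta_hat),
    se = ses, pvalue = p, n = n_total,
    stringsAsFactors = FALSE
  )
  summary_dataset(rec, trait_name = trait_name, trait_type = trait_type,
                  n_total = n_total, validate = FALSE)
}

#' Simulate a three-trait GWAS summary-statistics chain
#'
#' Generates exposure, mediator and outcome summary datasets consistent
#' with a linear causal chain. Each exposure instrument `j` has a true
#' per-allele effect `gamma_j` (magnitude drawn from
#' `gamma_range_exposure`, random sign) estimated with sampling error
#' `1/sqrt(2 maf (1 - maf) n)`; its true mediator effect is
#' `beta1 * gamma_j` and its true outcome effect
#' `(beta1 * beta2 + direct) * gamma_j` plus any pleiotropy term. The
#' mediator additionally carries its own independent instruments whose
#' outcome effects are `beta2 * delta_k`, and the outcome can carry its
#' own instruments (null for the other traits) for reverse-direction
#' checks. All three datasets share variant ids where the chain dictates;
#' the outcome is a binary trait on the log-odds scale with standard
#' errors governed by the effective sample size. Output is deterministic
#' given `scenario$seed`.
#'
#' @param scenario A [chain_scenario()].
#' @return List with elements `exposure`, `mediator`, `outcome`
#'   (`summary_dataset`s) and `truth` (scenario plus `true_total`,
#'   `true_indirect`, `true_direct`, `true_proportion`, and any
#'   pleiotropy outlier ids).
#' @export
simulate_chain <- function(scenario = chain_scenario()) {
  stopifnot(inherits(scenario, "chain_scenario"))
  sc <- scenario
  with_seed(sc$seed, {
    n_e <- sc$n_instruments_exposure
    n_m <- sc$n_instruments_mediator
    n_o <- sc$n_instruments_outcome

    # expand LD blocks into extra exposure-instrument slots
    n_extra <- 0L
    if (!is.null(sc$ld_blocks)) {
      lb <- sc$ld_blocks
      stopifnot(lb$n_blocks <= n_e, lb$size >= 2L, lb$r2 >= 0, lb$r2 < 1)
      n_extra <- lb$n_blocks * (lb$size - 1L)
    }
    total <- n_e + n_extra + n_m + n_o
    idx <- seq_len(total)
    layout <- snp_layout(idx)
    snps <- data.frame(
      variant_id = sprintf("rs%07d", idx),
      chromosome = layout$chromosome,
      position = layout$position,
      stringsAsFactors = FALSE
    )
    al <- draw_alleles(total, sc$frac_palindromic)
    snps$effect_allele <- al$effect
    snps$other_allele <- al$other
    snps$maf <- runif(total, sc$maf_range[1], sc$maf_range[2])

    e_idx <- seq_len(n_e)
    x_idx <- if (n_extra) n_e + seq_len(n_extra) else integer()
    m_idx <- n_e + n_extra + seq_len(n_m)
    o_idx <- n_e + n_extra + n_m + seq_len(n_o)

    draw_mag <- function(k, rng) {
      sample(c(-1, 1), k, replace = TRUE) * runif(k, rng[1], rng[2])
    }
    gamma <- numeric(total)
    gamma[e_idx] <- draw_mag(n_e, sc$gamma_range_exposure)
    delta <- numeric(total)
    if (n_m) delta[m_idx] <- draw_mag(n_m, sc$gamma_range_mediator)
    theta <- numeric(total)
    if (n_o) theta[o_idx] <- draw_mag(n_o, sc$gamma_range_outcome)

    ld <- NULL
    if (n_extra) {
      lb <- sc$ld_blocks
      r <- sqrt(lb$r2)
      ld_ids <- character()
      k <- 0L
      for (b in seq_len(lb$n_blocks)) {
        members <- x_idx[k + seq_len(lb$size - 1L)]
        k <- k + lb$size - 1L
        # place block members next to their index variant, correlated effects
        snps$chromosome[members] <- snps$chromosome[e_idx[b]]
        snps$position[members] <- snps$position[e_idx[b]] + 1e3 * seq_along(members)
        gamma[members] <- r * gamma[e_idx[b]]
        ld_ids <- c(ld_ids, snps$variant_id[c(e_idx[b], members)])
      }
      ld <- matrix(0, length(ld_ids), length(ld_ids),
                   dimnames = list(ld_ids, ld_ids))
      pos <- 0L
      for (b in seq_len(lb$n_blocks)) {
        block <- pos + seq_len(lb$size)
        ld[block, block] <- lb$r2
        diag(ld)[block] <- 1
        pos <- pos + lb$size
      }
    }

    # pleiotropy on the exposure instruments' outcome path
    alpha <- numeric(total)
    outlier_ids <- character()
    se_out_all <- se_gwas(snps$maf, sc$n_out_eff)
    pl <- sc$pleiotropy
    if (pl$type == "balanced") {
      alpha[e_idx] <- rnorm(n_e, 0, pl$sd)
    } else if (pl$type == "directional") {
      alpha[e_idx] <- rnorm(n_e, pl$mean, pl$sd)
    } else if (pl$type == "outlier" && pl$k > 0) {
      hit <- sample(e_idx, min(pl$k, n_e))
      alpha[hit] <- pl$shift * se_out_all[hit]
      outlier_ids <- snps$variant_id[hit]
    }

    # pleiotropy is defined on the exposure-increasing allele, so its sign
    # follows the instrument orientation (the Egger-intercept convention)
    orient <- ifelse(gamma < 0, -1, 1)
    mu_exp <- gamma
    mu_med <- sc$beta1 * gamma + delta
    mu_out <- (sc$beta1 * sc$beta2 + sc$direct) * gamma +
      sc$beta2 * delta + theta + orient * alpha

    exposure <- emit_gwas(snps, mu_exp, se_gwas(snps$maf, sc$n_exp),
                          "exposure", "continuous", sc$n_exp, scramble = 0)
    mediator <- emit_gwas(snps, mu_med, se_gwas(snps$maf, sc$n_med),
                          "mediator", "continuous", sc$n_med)
    outcome <- emit_gwas(snps, mu_out, se_out_all,
                         "outcome", "binary",
                         sc$n_out_cases + sc$n_out_controls)
    if (!is.null(ld)) attr(exposure, "ld") <- ld

    list(
      exposure = exposure, mediator = mediator, outcome = outcome,
      truth = list(
        scenario = sc,
        true_total = sc$true_total, true_indirect = sc$true_indirect,
        true_direct = sc$true_direct,
        true_proportion = sc$true_proportion,
        outlier_ids = outlier_ids,
        # per-variant true effects on the canonical (pre-scramble) allele
        true_effects = list(
          exposure = stats::setNames(mu_exp, snps$variant_id),
          mediator = stats::setNames(mu_med, snps$variant_id),
          outcome = stats::setNames(mu_out, snps$variant_id)
        )
      )
    )
  })
}

#' Simulate a mediator-screening study
#'
#' Generates one exposure, one outcome and a panel of candidate mediator
#' GWAS datasets of which `n_true` carry the causal chain
#' (`beta1`, `beta2` from the scenario) and the rest are null. Every
#' mediator dataset contains the exposure instruments (so step-1 screening
#' can harmonize against it) plus its own independent instruments (so
#' step-2 screening can instrument the mediator); the outcome dataset
#' contains the exposure instruments and all mediator instruments. A
#' fraction of the null mediators is given `X-`-prefixed names to emulate
#' unidentified metabolites.
#'
#' @param scenario A [chain_scenario()]; `beta1`, `beta2`, `direct` apply
#'   to each true mediator's chain.
#' @param n_mediators Number of candidate mediators (default 50, a
#'   desk-scale stand-in for a metabolome-wide panel).
#' @param n_true Number of mediators carrying a true chain (default 5).
#' @param unnamed_fraction Fraction of null mediators given unnamed
#'   (`X-`) labels.
#' @param seed Seed; defaults to the scenario's.
#' @return List with `exposure`, `mediators` (named list), `outcome`, and
#'   `truth` (`true_mediators`, per-chain effects, totals). The true total
#'   exposure-outcome effect is `direct + n_true * beta1 * beta2`.
#' @export
simulate_mediation_study <- function(scenario = chain_scenario(),
                                     n_mediators = 50L, n_true = 5L,
                                     unnamed_fraction = 0.10,
                                     seed = scenario$seed) {
  stopifnot(inherits(scenario, "chain_scenario"),
            n_true >= 0, n_true <= n_mediators)
  sc <- scenario
  with_seed(seed, {
    n_e <- sc$n_instruments_exposure
    n_im <- sc$n_instruments_mediator
    total <- n_e + n_mediators * n_im
    idx <- seq_len(total)
    layout <- snp_layout(idx)
    snps <- data.frame(
      variant_id = sprintf("rs%07d", idx),
      chromosome = layout$chromosome,
      position = layout$position,
      stringsAsFactors = FALSE
    )
    al <- draw_alleles(total, sc$frac_palindromic)
    snps$effect_allele <- al$effect
    snps$other_allele <- al$other
    snps$maf <- runif(total, sc$maf_range[1], sc$maf_range[2])

    e_idx <- seq_len(n_e)
    gamma <- numeric(total)
    gamma[e_idx] <- sample(c(-1, 1), n_e, replace = TRUE) *
      runif(n_e, sc$gamma_range_exposure[1], sc$gamma_range_exposure[2])

    which_true <- sort(sample.int(n_mediators, n_true))
    med_names <- sprintf("met_%03d", seq_len(n_mediators))
    null_ids <- setdiff(seq_len(n_mediators), which_true)
    n_unnamed <- floor(unnamed_fraction * length(null_ids))
    if (n_unnamed > 0) {
      unnamed <- sample(null_ids, n_unnamed)
      med_names[unnamed] <- sprintf("X-%05d", 25000 + unnamed)
    }

    se_exp <- se_gwas(snps$maf, sc$n_exp)
    se_med <- se_gwas(snps$maf, sc$n_med)
    se_out <- se_gwas(snps$maf, sc$n_out_eff)

    # pleiotropy on the exposure instruments' outcome path
    alpha <- numeric(total)
    pl <- sc$pleiotropy
    if (pl$type == "balanced") {
      alpha[e_idx] <- rnorm(n_e, 0, pl$sd)
    } else if (pl$type == "directional") {
      alpha[e_idx] <- rnorm(n_e, pl$mean, pl$sd)
    } else if (pl$type == "outlier" && pl$k > 0) {
      hit <- sample(e_idx, min(pl$k, n_e))
      alpha[hit] <- pl$shift * se_out[hit]
    }

    exposure <- emit_gwas(snps[e_idx, , drop = FALSE], gamma[e_idx],
                          se_exp[e_idx], "exposure", "continuous",
                          sc$n_exp, scramble = 0)

    orient <- ifelse(gamma < 0, -1, 1)
    mu_out <- (sc$direct + n_true * sc$beta1 * sc$beta2) * gamma +
      orient * alpha
    mediators <- vector("list", n_mediators)
    for (m in seq_len(n_mediators)) {
      own_idx <- n_e + (m - 1L) * n_im + seq_len(n_im)
      is_true <- m %in% which_true
      delta <- sample(c(-1, 1), n_im, replace = TRUE) *
        runif(n_im, sc$gamma_range_mediator[1], sc$gamma_range_mediator[2])
      rows <- c(e_idx, own_idx)
      mu_m <- numeric(length(rows))
      if (is_true) mu_m[seq_len(n_e)] <- sc$beta1 * gamma[e_idx]
      mu_m[n_e + seq_len(n_im)] <- delta
      mediators[[m]] <- emit_gwas(snps[rows, , drop = FALSE], mu_m,
                                  se_med[rows], med_names[m], "continuous",
                                  sc$n_med)
      if (is_true) mu_out[own_idx] <- sc$beta2 * delta
    }
    names(mediators) <- med_names

    outcome <- emit_gwas(snps, mu_out, se_out, "outcome", "binary",
                         sc$n_out_cases + sc$n_out_controls)

    true_total <- sc$direct + n_true * sc$beta1 * sc$beta2
    list(
      exposure = exposure, mediators = mediators, outcome = outcome,
      truth = list(
        scenario = sc, true_mediators = med_names[which_true],
        beta1 = sc$beta1, beta2 = sc$beta2,
        true_total = true_total,
        true_indirect_each = sc$beta1 * sc$beta2,
        true_proportion_each = if (true_total != 0)
          sc$beta1 * sc$beta2 / true_total else NA_real_
      )
    )
  })
}

#' Inject outlier shifts into a summary dataset
#'
#' Shifts the effect of `k` randomly chosen variants by `shift_sd` standard
#' errors (p-values are recomputed to stay consistent); used to exercise
#' the outlier diagnostics. Modified variant ids are recorded in the
#' `outlier_ids` attribute.
#'
#' @param ds A `summary_dataset`.
#' @param k Number of variants to shift (`k <= nrow(ds)`).
#' @param shift_sd Shift size in units of each variant's standard error.
#' @param seed Optional seed.
#' @return The modified `summary_dataset`.
#' @export
inject_outliers <- function(ds, k, shift_sd, seed = NULL) {
  stopifnot(inherits(ds, "summary_dataset"), k >= 0, k <= nrow(ds))
  if (k == 0) {
    attr(ds, "outlier_ids") <- character()
    return(ds)
  }
  with_seed(seed, {
    idx <- sample.int(nrow(ds), k)
    ds$beta[idx] <- ds$beta[idx] + shift_sd * ds$se[idx]
    ds$pvalue[idx] <- pmax(2 * pnorm(-abs(ds$beta[idx] / ds$se[idx])), 1e-300)
    attr(ds, "outlier_ids") <- ds$variant_id[idx]
    ds
  })
}

#' Simulate a multi-exposure (taxa-panel) study
#'
#' Generates a panel of exposure GWAS datasets — emulating a collection of
#' microbial taxa — of which `n_true` have a genuine total effect
#' (`beta1 * beta2 + direct` from the scenario) on a shared binary
#' outcome, and the rest are null. Each exposure has its own independent
#' instruments; the outcome dataset contains all of them. Supports
#' forward-screening validation across many exposures.
#'
#' @param scenario A [chain_scenario()].
#' @param n_exposures Number of exposure traits (default 10).
#' @param n_true Number with a true effect on the outcome (default 1).
#' @param seed Seed; defaults to the scenario's.
#' @return List with `exposures` (named list of `summary_dataset`s),
#'   `outcome`, and `truth` (`true_exposures`, `true_total`).
#' @export
simulate_taxa_study <- function(scenario = chain_scenario(),
                                n_exposures = 10L, n_true = 1L,
                                seed = scenario$seed) {
  stopifnot(inherits(scenario, "chain_scenario"),
            n_true >= 0, n_true <= n_exposures)
  sc <- scenario
  with_seed(seed, {
    n_ie <- sc$n_instruments_exposure
    total <- n_exposures * n_ie
    idx <- seq_len(total)
    layout <- snp_layout(idx)
    snps <- data.frame(
      variant_id = sprintf("rs%07d", idx),
      chromosome = layout$chromosome,
      position = layout$position,
      stringsAsFactors = FALSE
    )
    al <- draw_alleles(total, sc$frac_palindromic)
    snps$effect_allele <- al$effect
    snps$other_allele <- al$other
    snps$maf <- runif(total, sc$maf_range[1], sc$maf_range[2])

    which_true <- sort(sample.int(n_exposures, n_true))
    exp_names <- sprintf("taxon_%03d", seq_len(n_exposures))
    se_exp <- se_gwas(snps$maf, sc$n_exp)
    se_out <- se_gwas(snps$maf, sc$n_out_eff)

    mu_out <- numeric(total)
    exposures <- vector("list", n_exposures)
    for (t in seq_len(n_exposures)) {
      own <- (t - 1L) * n_ie + seq_len(n_ie)
      gamma <- sample(c(-1, 1), n_ie, replace = TRUE) *
        runif(n_ie, sc$gamma_range_exposure[1], sc$gamma_range_exposure[2])
      exposures[[t]] <- emit_gwas(snps[own, , drop = FALSE], gamma,
                                  se_exp[own], exp_names[t], "continuous",
                                  sc$n_exp, scramble = 0)
      if (t %in% which_true) mu_out[own] <- sc$true_total * gamma
    }
    names(exposures) <- exp_names
    outcome <- emit_gwas(snps, mu_out, se_out, "outcome", "binary",
                         sc$n_out_cases + sc$n_out_controls)
    list(
      exposures = exposures, outcome = outcome,
      truth = list(scenario = sc, true_exposures = exp_names[which_true],
                   true_total = sc$true_total)
    )
  })
}
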