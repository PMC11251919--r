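# Shared fixtures and independent oracle implementations used across tests.

# Harmonized-instrument table from raw effect vectors.
make_insts <- function(g, sg, G, sG, id = paste0("v", seq_along(g))) {
  data.frame(variant_id = id,
             beta_exposure = g, se_exposure = sg,
             beta_outcome = G, se_outcome = sG,
             stringsAsFactors = FALSE)
}

# Random small harmonized instance (caller controls the RNG seed).
random_instruments <- function(j) {
  g <- runif(j, 0.05, 0.4) * sample(c(-1, 1), j, replace = TRUE)
  make_insts(g,
             sg = runif(j, 0.005, 0.05),
             G = rnorm(j, 0, 0.2),
             sG = runif(j, 0.02, 0.3))
}

# Independent IVW oracle: inverse-variance-weighted mean of Wald ratios.
ivw_oracle <- function(insts) {
  ratios <- insts$beta_outcome / insts$beta_exposure
  w <- insts$beta_exposure^2 / insts$se_outcome^2
  sum(w * ratios) / sum(w)
}

# Independent weighted-median oracle: explicit loop over the midpoint
# cumulative-weight rule with linear interpolation at 0.5.
weighted_median_oracle <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o]
  total <- sum(w)
  s <- numeric(length(b))
  cum <- 0
  for (j in seq_along(b)) {
    s[j] <- (cum + w[j] / 2) / total
    cum <- cum + w[j]
  }
  if (s[1] >= 0.5) return(b[1])
  if (s[length(s)] <= 0.5) return(b[length(b)])
  for (j in seq_along(b)[-1]) {
    if (s[j] >= 0.5) {
      return(b[j - 1] + (b[j] - b[j - 1]) * (0.5 - s[j - 1]) / (s[j] - s[j - 1]))
    }
  }
}

# Small hand-built summary dataset; each variant on its own chromosome slot
# unless chromosome/position are supplied.
make_ds <- function(n = 3, trait = "trait", pvalue = NULL, beta = NULL,
                    se = NULL, eaf = NULL, chromosome = NULL,
                    position = NULL, effect_allele = NULL,
                    other_allele = NULL, n_total = 10000, validate = TRUE,
                    trait_type = "continuous") {
  se <- se %||% rep(0.02, n)
  if (is.null(beta)) {
    # derive beta from the requested p so beta/se and p stay consistent
    beta <- if (is.null(pvalue)) rep(0.1, n)
            else se * qnorm(pvalue / 2, lower.tail = FALSE)
  }
  pvalue <- pvalue %||% pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  summary_dataset(data.frame(
    variant_id = paste0("rs", seq_len(n)),
    chromosome = chromosome %||% as.character(((seq_len(n) - 1) %% 22) + 1),
    position = position %||% (1e6 + 2.5e7 * ((seq_len(n) - 1) %/% 22)),
    effect_allele = effect_allele %||% rep("A", n),
    other_allele = other_allele %||% rep("G", n),
    eaf = eaf %||% rep(0.3, n),
    beta = beta, se = se, pvalue = pvalue, n = n_total,
    stringsAsFactors = FALSE
  ), trait_name = trait, trait_type = trait_type, n_total = n_total,
  validate = validate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Instrument preparation shorthand used by pipeline-level tests.
prep_iv <- function(ds, p_threshold = 1e-5, ld = NULL) {
  suppressMessages(suppressWarnings(
    clump_instruments(select_instruments(ds, p_threshold), ld = ld)
  ))
}
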