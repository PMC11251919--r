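# Allele pair fixture covering every harmonization path:
#   rs1 same orientation, rs2 swapped, rs3 strand-complemented,
#   rs4 palindromic, rs5 incompatible, rs6 absent from the outcome.
fixture_pair <- function() {
  exposure <- make_ds(6,
    effect_allele = c("A", "A", "A", "A", "A", "A"),
    other_allele  = c("G", "G", "G", "T", "G", "G"),
    beta = rep(0.1, 6), trait = "exposure")
  out_rec <- data.frame(
    variant_id = paste0("rs", 1:5),
    chromosome = as.character(1:5), position = rep(1e6, 5),
    effect_allele = c("A", "G", "T", "A", "A"),
    other_allele  = c("G", "A", "C", "T", "C"),
    eaf = c(0.3, 0.7, 0.3, 0.3, 0.3),
    beta = c(0.05, 0.05, 0.05, 0.05, 0.05),
    se = rep(0.02, 5), pvalue = rep(0.0124, 5), n = 5000,
    stringsAsFactors = FALSE
  )
  outcome <- summary_dataset(out_rec, trait_name = "outcome")
  list(exposure = exposure, outcome = outcome)
}

test_that("palindromic pairs are exactly A/T and C/G", {
  expect_true(all(is_palindromic(c("A", "T", "C", "G"), c("T", "A", "G", "C"))))
  expect_false(any(is_palindromic(c("A", "A", "C", "G"), c("G", "C", "T", "T"))))
})

test_that("harmonization aligns, flips, complements, and removes variants", {
  fx <- fixture_pair()
  h <- harmonize_pair(fx$exposure, fx$outcome)
  lg <- harmonization_log(h)

  expect_equal(sort(h$variant_id), c("rs1", "rs2", "rs3"))
  # identical orientation: outcome effect unchanged
  expect_equal(h$beta_outcome[h$variant_id == "rs1"], 0.05)
  # swapped orientation: negated effect, flipped frequency
  expect_equal(h$beta_outcome[h$variant_id == "rs2"], -0.05)
  expect_equal(h$eaf_outcome[h$variant_id == "rs2"], 0.3)
  # strand complement (T/C -> A/G): kept as-is after complementing
  expect_equal(h$beta_outcome[h$variant_id == "rs3"], 0.05)

  expect_equal(lg$n_input, 6L)
  expect_equal(lg$n_matched, 3L)
  expect_equal(lg$n_flipped, 1L)
  expect_equal(lg$n_palindromic_removed, 1L)
  expect_equal(lg$n_incompatible_removed, 1L)
  expect_equal(lg$n_unmatched, 1L)
  # conservation: the counts partition the input exactly
  expect_equal(lg$n_matched + lg$n_palindromic_removed +
                 lg$n_incompatible_removed + lg$n_unmatched, lg$n_input)
})

test_that("harmonization is invariant to outcome allele orientation", {
  fx <- fixture_pair()
  flipped_rec <- as.data.frame(fx$outcome)
  tmp <- flipped_rec$effect_allele
  flipped_rec$effect_allele <- flipped_rec$other_allele
  flipped_rec$other_allele <- tmp
  flipped_rec$beta <- -flipped_rec$beta
  flipped_rec$eaf <- 1 - flipped_rec$eaf
  flipped <- suppressWarnings(summary_dataset(flipped_rec, trait_name = "outcome"))

  h1 <- harmonize_pair(fx$exposure, fx$outcome)
  h2 <- harmonize_pair(fx$exposure, flipped)
  o1 <- as.data.frame(h1)[order(h1$variant_id), ]
  o2 <- as.data.frame(h2)[order(h2$variant_id), ]
  rownames(o1) <- rownames(o2) <- NULL
  # the harmonized set is identical; only the flip bookkeeping may differ
  expect_equal(o2, o1, ignore_attr = TRUE)
})

test_that("harmonizing an already-harmonized pair changes nothing", {
  fx <- fixture_pair()
  h <- harmonize_pair(fx$exposure, fx$outcome)
  # rebuild both sides from the harmonized table
  e2 <- summary_dataset(data.frame(
    variant_id = h$variant_id, effect_allele = h$effect_allele,
    other_allele = h$other_allele, eaf = h$eaf_exposure,
    beta = h$beta_exposure, se = h$se_exposure, pvalue = h$pval_exposure
  ), trait_name = "exposure")
  o2 <- summary_dataset(data.frame(
    variant_id = h$variant_id, effect_allele = h$effect_allele,
    other_allele = h$other_allele, eaf = h$eaf_outcome,
    beta = h$beta_outcome, se = h$se_outcome, pvalue = h$pval_outcome
  ), trait_name = "outcome", validate = FALSE)
  h2 <- harmonize_pair(e2, o2)
  lg2 <- harmonization_log(h2)
  expect_equal(lg2$n_flipped, 0L)
  expect_equal(lg2$n_palindromic_removed, 0L)
  expect_equal(lg2$n_matched, nrow(h))
  expect_equal(h2$beta_outcome[order(h2$variant_id)],
               h$beta_outcome[order(h$variant_id)])
})

test_that("frequency-based inference can rescue unambiguous palindromic variants", {
  e <- make_ds(3, effect_allele = rep("A", 3), other_allele = rep("T", 3),
               eaf = c(0.1, 0.1, 0.5), trait = "exposure")
  o_rec <- data.frame(
    variant_id = paste0("rs", 1:3),
    chromosome = as.character(1:3), position = rep(1e6, 3),
    effect_allele = rep("A", 3), other_allele = rep("T", 3),
    eaf = c(0.1, 0.9, 0.5), beta = rep(0.05, 3), se = rep(0.02, 3),
    pvalue = rep(0.0124, 3), n = 5000, stringsAsFactors = FALSE
  )
  o <- summary_dataset(o_rec, trait_name = "outcome")

  # default mode removes all three
  expect_error(harmonize_pair(e, o), "zero harmonized")

  h <- harmonize_pair(e, o, palindromic = "infer")
  lg <- harmonization_log(h)
  # rs1: frequencies agree -> kept; rs2: opposite side -> strand flip;
  # rs3: 0.5 is inside the ambiguity band -> still removed
  expect_equal(sort(h$variant_id), c("rs1", "rs2"))
  expect_equal(h$beta_outcome[h$variant_id == "rs1"], 0.05)
  expect_equal(h$beta_outcome[h$variant_id == "rs2"], -0.05)
  expect_equal(lg$n_palindromic_removed, 1L)
  expect_equal(lg$n_flipped, 1L)
})

test_that("harmonization conserves counts on simulated consortium-style data", {
  for (seed in 1:5) {
    sim <- simulate_chain(chain_scenario(n_instruments_exposure = 40,
                                         n_instruments_mediator = 10,
                                         seed = seed))
    iv <- prep_iv(sim$exposure)
    h <- harmonize_pair(iv, sim$outcome)
    lg <- harmonization_log(h)
    expect_equal(lg$n_matched + lg$n_palindromic_removed +
                   lg$n_incompatible_removed + lg$n_unmatched, lg$n_input)
    expect_equal(lg$n_matched, nrow(h))
    # no palindromic pair survives default harmonization
    expect_false(any(is_palindromic(h$effect_allele, h$other_allele)))
  }
})

test_that("an empty harmonized set names both traits in its error", {
  e <- make_ds(2, effect_allele = c("A", "C"), other_allele = c("T", "G"),
               trait = "bugs")
  o <- make_ds(2, effect_allele = c("A", "C"), other_allele = c("T", "G"),
               trait = "tumour")
  expect_error(harmonize_pair(e, o), "bugs.*tumour")
})
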