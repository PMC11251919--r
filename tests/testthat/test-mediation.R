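test_that("decomposition conserves total = direct + indirect exactly", {
  set.seed(61)
  for (i in 1:25) {
    total <- rnorm(1)
    b1 <- rnorm(1)
    b2 <- rnorm(1)
    res <- decompose_effect(total, b1, b2)
    expect_equal(res$direct + res$indirect, total, tolerance = 1e-14)
    expect_equal(res$proportion, b1 * b2 / total, tolerance = 1e-15)
  }

  # no mediation when the first-step effect vanishes
  res0 <- decompose_effect(0.4, b1 = 0, b2 = 0.7)
  expect_equal(res0$indirect, 0)
  expect_equal(res0$direct, 0.4)
  expect_equal(res0$proportion, 0)

  # zero total effect: proportion undefined but fields returned
  expect_warning(rz <- decompose_effect(0, b1 = 0.1, b2 = 0.2), "undefined")
  expect_true(is.na(rz$proportion))
  expect_equal(rz$indirect, 0.02)
})

test_that("the product-of-coefficients delta se behaves as the formula says", {
  expect_equal(indirect_se_delta(0, 0.1, 0, 0.2), 0)
  expect_equal(indirect_se_delta(1, 0.1, 0, 0.2), 0.2)
  # symmetric under swapping the two coefficients
  expect_equal(indirect_se_delta(0.3, 0.05, -0.7, 0.12),
               indirect_se_delta(-0.7, 0.12, 0.3, 0.05))
  expect_equal(indirect_se_delta(2, 0.1, 3, 0.2),
               sqrt(9 * 0.01 + 4 * 0.04), tolerance = 1e-15)
  expect_error(indirect_se_delta(1, 0, 1, 0.1), "se1")

  se_p <- proportion_se_delta(0.5, 0.05, 0.3, 0.02, 0.4, 0.03)
  expect_equal(se_p, sqrt((0.4 * 0.02 / 0.5)^2 + (0.3 * 0.03 / 0.5)^2 +
                            (0.12 * 0.05 / 0.25)^2), tolerance = 1e-15)
})

test_that("step-1 screening finds true mediators and respects alpha", {
  st <- simulate_mediation_study(chain_scenario(seed = 71),
                                 n_mediators = 20, n_true = 5,
                                 unnamed_fraction = 0)
  iv <- prep_iv(st$exposure)
  s1 <- screen_step1(iv, st$mediators)
  expect_equal(nrow(s1), 20L)
  hits <- sum(s1$passed & s1$mediator %in% st$truth$true_mediators)
  expect_gte(hits, 4L)

  # boundary: alpha just below 1 passes every mediator with instruments
  s1_all <- screen_step1(iv, st$mediators, alpha = 1 - 1e-12)
  expect_true(all(s1_all$passed[s1_all$reason == "ok"]))

  # monotonicity: lowering alpha never adds a passer
  s1_strict <- screen_step1(iv, st$mediators, alpha = 0.001)
  expect_true(all(s1$passed[s1_strict$passed]))
})

test_that("step-1 screening holds its type-I error on null mediators", {
  rates <- vapply(1:10, function(s) {
    st <- simulate_mediation_study(chain_scenario(seed = 600 + s),
                                   n_mediators = 30, n_true = 0,
                                   unnamed_fraction = 0)
    s1 <- screen_step1(prep_iv(st$exposure), st$mediators)
    mean(s1$passed)
  }, numeric(1))
  expect_gt(mean(rates), 0.005)
  expect_lt(mean(rates), 0.12)
})

test_that("a mediator without harmonizable instruments is reported, not fatal", {
  st <- simulate_mediation_study(chain_scenario(seed = 72),
                                 n_mediators = 3, n_true = 1)
  iv <- prep_iv(st$exposure)
  # a mediator GWAS sharing no variant ids with the exposure instruments
  orphan <- make_ds(5, trait = "orphan")
  orphan$variant_id <- paste0("rsX", 1:5)
  meds <- c(st$mediators, list(orphan = orphan))
  s1 <- screen_step1(iv, meds)
  expect_equal(s1$reason[s1$mediator == "orphan"], "no instruments")
  expect_false(s1$passed[s1$mediator == "orphan"])
})

# Two candidate mediators, both truly affecting the outcome, where the
# unnamed one ("X-...") carries the stronger effect and hence the smaller p.
two_mediator_fixture <- function(seed = 81, b2 = c(0.4, 0.9)) {
  st1 <- simulate_chain(chain_scenario(seed = seed, beta2 = b2[1]))
  st2 <- simulate_chain(chain_scenario(seed = seed + 500, beta2 = b2[2]))
  # merge the two chains into one outcome; the second chain's variant ids
  # are prefixed to keep the two instrument sets distinct
  shift_ids <- function(ds, tag) {
    ds$variant_id <- paste0(tag, ds$variant_id)
    ds
  }
  med2 <- shift_ids(st2$mediator, "b")
  out_rec <- rbind(as.data.frame(st1$outcome),
                   as.data.frame(shift_ids(st2$outcome, "b")))
  outcome <- summary_dataset(out_rec, trait_name = "outcome",
                             trait_type = "binary", validate = FALSE)
  list(mediators = list(named_met = st1$mediator, `X-11111` = med2),
       outcome = outcome)
}

test_that("step-2 screening applies the unnamed exclusion and smallest-p rules", {
  fx <- two_mediator_fixture()
  s1 <- data.frame(mediator = c("named_met", "X-11111"),
                   n_snp = c(30L, 30L), beta1 = c(0.3, 0.3),
                   se1 = c(0.05, 0.05), p_step1 = c(1e-4, 1e-4),
                   passed = c(TRUE, TRUE), reason = "ok",
                   stringsAsFactors = FALSE)
  s2 <- screen_step2(s1, fx$mediators, fx$outcome)
  expect_true(all(s2$passed == c(TRUE, FALSE)))
  expect_equal(s2$reason[s2$mediator == "X-11111"], "unnamed")
  # the unnamed mediator would have won on p alone
  expect_lt(s2$p_step2[s2$mediator == "X-11111"],
            s2$p_step2[s2$mediator == "named_met"])
  expect_true(s2$selected[s2$mediator == "named_met"])

  # with the exclusion off, the smallest p wins
  s2_incl <- screen_step2(s1, fx$mediators, fx$outcome,
                          exclude_unnamed = FALSE)
  expect_true(s2_incl$selected[s2_incl$mediator == "X-11111"])

  # selection respects "selected => passed => named (when excluding)"
  expect_true(all(!s2$selected | s2$passed))
  expect_true(all(!s2$passed | s2$named))
})

test_that("two named passers resolve to the smaller step-2 p-value", {
  fx <- two_mediator_fixture()
  names(fx$mediators) <- c("met_A", "met_B")
  s1 <- data.frame(mediator = c("met_A", "met_B"), n_snp = 30L,
                   beta1 = 0.3, se1 = 0.05, p_step1 = 1e-4, passed = TRUE,
                   reason = "ok", stringsAsFactors = FALSE)
  s2 <- screen_step2(s1, fx$mediators, fx$outcome)
  expect_equal(sum(s2$selected), 1L)
  expect_equal(s2$mediator[s2$selected],
               s2$mediator[which.min(s2$p_step2)])
})

test_that("no significant mediator yields an empty selection", {
  st <- simulate_mediation_study(chain_scenario(seed = 83, beta2 = 0),
                                 n_mediators = 4, n_true = 1,
                                 unnamed_fraction = 0)
  iv <- prep_iv(st$exposure)
  s1 <- screen_step1(iv, st$mediators)
  s2 <- screen_step2(s1, st$mediators, st$outcome)
  expect_false(any(s2$selected))
})
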