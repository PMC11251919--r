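test_that("read_sumstats parses well-formed tables and drops invalid rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "SNP\tchr\tpos\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn",
    "rs1\t1\t1000\tA\tG\t0.3\t0.10\t0.02\t5.7e-7\t10000",
    "rs2\t2\t2000\tC\tT\t0.2\t-0.05\t0.01\t5.7e-7\t10000",
    "rs3\t3\t3000\tG\tA\t0.4\t0.02\t0.02\t0.317\t10000"
  ), path)
  ds <- read_sumstats(path, trait_name = "toy")
  expect_s3_class(ds, "summary_dataset")
  expect_equal(nrow(ds), 3L)
  expect_equal(attr(ds, "n_dropped"), 0L)
  expect_equal(attr(ds, "trait_name"), "toy")

  # invalid rows (zero se, identical alleles) are dropped and counted
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "SNP\tchr\tpos\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn",
    "rs1\t1\t1000\tA\tG\t0.3\t0.10\t0.02\t5.7e-7\t10000",
    "rs2\t2\t2000\tC\tC\t0.2\t-0.05\t0.01\t5.7e-7\t10000",
    "rs3\t3\t3000\tG\tA\t0.4\t0.02\t0\t0.317\t10000"
  ), bad)
  expect_message(ds2 <- read_sumstats(bad), "dropped 2 invalid")
  expect_equal(nrow(ds2), 1L)
  expect_equal(attr(ds2, "n_dropped"), 2L)
})

test_that("read_sumstats reports missing mandatory columns and empty files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("SNP,beta,se,pval", "rs1,0.1,0.02,1e-6"), path)
  expect_error(read_sumstats(path), "effect_allele")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  expect_error(read_sumstats(empty), "empty")

  header_only <- withr::local_tempfile(fileext = ".tsv")
  writeLines("SNP\teffect_allele\tother_allele\tbeta\tse\tpval", header_only)
  expect_error(read_sumstats(header_only), "no data rows")
})

test_that("write_sumstats round-trips through read_sumstats", {
  ds <- make_ds(5, beta = seq(0.05, 0.25, by = 0.05))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(ds, path)
  back <- read_sumstats(path, trait_name = attr(ds, "trait_name"))
  expect_equal(back$beta, ds$beta)
  expect_equal(back$variant_id, ds$variant_id)
})

test_that("inconsistent reported p-values warn but are kept", {
  rec <- data.frame(variant_id = "rs1", effect_allele = "A",
                    other_allele = "G", beta = 0.1, se = 0.02,
                    pvalue = 0.5)  # true p ~ 5.7e-7
  expect_warning(ds <- summary_dataset(rec), "inconsistent")
  expect_equal(nrow(ds), 1L)
  expect_equal(ds$pvalue, 0.5)
})

test_that("select_instruments filters strictly and idempotently", {
  ds <- make_ds(3, pvalue = c(1e-6, 2e-5, 0.5))
  kept <- select_instruments(ds, 1e-5)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$pvalue, 1e-6)

  # threshold just below 1 keeps everything
  expect_equal(nrow(select_instruments(ds, 1 - 1e-12)), 3L)

  # reverse-threshold count is a direct filter
  ds30 <- make_ds(30, pvalue = runif(30, 1e-8, 4.9e-5))
  expect_equal(nrow(select_instruments(ds30, 5e-5)), 30L)

  # idempotence at the same threshold
  expect_equal(as.data.frame(select_instruments(kept, 1e-5)),
               as.data.frame(kept))

  # monotonicity: a stricter threshold never adds a variant
  loose <- select_instruments(ds, 1e-4)
  strict <- suppressWarnings(select_instruments(ds, 1e-6))
  expect_true(all(strict$variant_id %in% loose$variant_id))

  expect_error(select_instruments(ds, 0), "p_threshold")
  expect_warning(select_instruments(ds, 1e-30), "no instruments")
})

test_that("clumping respects the window, chromosome boundaries, and LD", {
  # two variants 1 kb apart: the smaller p wins under distance clumping
  ds <- make_ds(2, chromosome = c("1", "1"), position = c(1e6, 1e6 + 1000),
                pvalue = c(1e-6, 1e-8))
  expect_message(out <- clump_instruments(ds), "distance-only")
  expect_equal(nrow(out), 1L)
  expect_equal(out$pvalue, 1e-8)

  # the same pair with supplied r2 = 0.5 >= 0.001 is still pruned
  ld <- matrix(c(1, 0.5, 0.5, 1), 2, 2,
               dimnames = list(c("rs1", "rs2"), c("rs1", "rs2")))
  out_ld <- clump_instruments(ds, ld = ld)
  expect_equal(nrow(out_ld), 1L)

  # r2 below the threshold keeps both despite the shared window
  ld_lo <- matrix(c(1, 5e-4, 5e-4, 1), 2, 2,
                  dimnames = list(c("rs1", "rs2"), c("rs1", "rs2")))
  expect_equal(nrow(clump_instruments(ds, ld = ld_lo)), 2L)

  # windows never span chromosomes
  ds2 <- make_ds(2, chromosome = c("1", "2"), position = c(1e6, 1e6 + 1000),
                 pvalue = c(1e-6, 1e-8))
  expect_equal(nrow(suppressMessages(clump_instruments(ds2))), 2L)
})

test_that("a fully correlated block collapses to its smallest-p variant", {
  set.seed(41)
  p <- runif(10, 1e-10, 1e-5)
  ds <- make_ds(10, chromosome = rep("7", 10),
                position = 1e6 + (0:9) * 1000, pvalue = p)
  ids <- ds$variant_id
  ld <- matrix(0.9, 10, 10, dimnames = list(ids, ids))
  diag(ld) <- 1
  out <- clump_instruments(ds, ld = ld)
  expect_equal(nrow(out), 1L)
  # brute force: every greedy step removes the rest, so the argmin-p survives
  expect_equal(out$variant_id, ds$variant_id[which.min(ds$pvalue)])

  # input row order cannot matter: rebuild from shuffled records
  shuffled <- summary_dataset(as.data.frame(ds)[sample(10), ],
                              trait_name = "trait")
  out2 <- suppressMessages(clump_instruments(shuffled, ld = ld))
  expect_equal(out2$variant_id, out$variant_id)
})

test_that("variance explained follows 2p(1-p)beta^2 and clips to [0,1)", {
  expect_equal(variance_explained(data.frame(eaf = 0.5, beta = 0)), 0)
  expect_equal(variance_explained(data.frame(eaf = 0.5, beta = 0.2)), 0.02)
  # monomorphic limit
  expect_lt(variance_explained(data.frame(eaf = 1e-9, beta = 0.2)), 1e-9)
  expect_lt(variance_explained(data.frame(eaf = 0.5, beta = 100)), 1)
  expect_error(variance_explained(data.frame(eaf = NA_real_, beta = 0.1)),
               "supply eaf")
})

test_that("the F statistic follows R2(n-k-1)/(k(1-R2)) with a weak flag", {
  expect_equal(f_statistic(0, 1000, 5)$f_stat, 0)
  expect_true(f_statistic(0, 1000, 5)$weak)

  fs <- f_statistic(0.01, 18340, 10)
  expect_equal(fs$f_stat, 0.01 * 18329 / (10 * 0.99), tolerance = 1e-12)
  expect_equal(fs$f_stat, 18.514, tolerance = 1e-3)
  expect_false(fs$weak)

  expect_equal(f_statistic(0.5, 102, 1)$f_stat, 100)

  # strictly increasing in R2, strictly decreasing in k
  expect_gt(f_statistic(0.02, 1000, 5)$f_stat,
            f_statistic(0.01, 1000, 5)$f_stat)
  expect_lt(f_statistic(0.01, 1000, 6)$f_stat,
            f_statistic(0.01, 1000, 5)$f_stat)

  expect_error(f_statistic(0.01, 6, 5), "domain")
  expect_error(f_statistic(1, 1000, 5), "r2_total")
})

test_that("single-instrument F approximates the squared Wald z at large n", {
  set.seed(7)
  n <- 10000
  maf <- 0.3
  g <- rbinom(n, 2, maf)
  g <- (g - mean(g)) / sd(g)
  y <- 0.06 * g + rnorm(n)
  fit <- summary(lm(y ~ g))
  z <- fit$coefficients["g", "t value"]
  f <- f_statistic(fit$r.squared, n, 1)$f_stat
  expect_equal(f, z^2, tolerance = 0.1)
})

test_that("instrument_strength aggregates per-variant R2 over the set", {
  ds <- make_ds(4, beta = c(0.1, 0.12, 0.08, 0.15), eaf = rep(0.25, 4))
  fs <- instrument_strength(ds)
  expect_equal(fs$k, 4L)
  expect_equal(fs$r2_total, sum(2 * 0.25 * 0.75 * ds$beta^2))
  per <- instrument_strength(ds, per_snp = TRUE)
  expect_equal(nrow(per), 4L)
  expect_equal(sum(per$r2), fs$r2_total)
})
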