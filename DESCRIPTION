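Package: mrchain
Title: Two-Sample Mendelian Randomization with Two-Step Mediation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) and two-step
    MR mediation analysis from GWAS summary statistics: instrument selection
    by significance, distance/LD clumping and F-statistics; allele
    harmonization with palindromic and incompatible variant handling; the
    inverse-variance-weighted, MR-Egger and weighted-median causal
    estimators; sensitivity diagnostics (Cochran's Q, Egger intercept,
    leave-one-out, MR-PRESSO global/outlier/distortion tests); mediator
    screening and coefficient-difference effect decomposition with
    delta-method uncertainty; and a seeded generator of summary statistics
    with a configurable exposure-mediator-outcome causal chain for
    validation without individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
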