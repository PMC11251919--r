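---
title: "Methods: two-sample MR and two-step mediation in mrchain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR and two-step mediation in mrchain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrchain)
```

# The model

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure on an outcome from two independent GWAS. For each instrument
(variant) $j$ we observe the exposure association $\hat\gamma_j$ with
standard error $\sigma_{\gamma j}$ and the outcome association
$\hat\Gamma_j$ with $\sigma_{\Gamma j}$, both expressed per copy of the
same effect allele. Under the instrumental-variable assumptions
(relevance, independence, exclusion restriction) each Wald ratio
$\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$ estimates the same causal
effect $\beta$.

For a mediation question the package assumes a linear chain
$X \to M \to Y$ with direct path $X \to Y$. The total effect $\beta$
decomposes as

$$\beta \;=\; \underbrace{\beta_1 \beta_2}_{\text{indirect}}
  \;+\; \underbrace{\beta - \beta_1\beta_2}_{\text{direct}},$$

where $\beta_1$ ($X \to M$) and $\beta_2$ ($M \to Y$) come from two
separate univariable MR fits (the coefficient-difference, two-step
design — deliberately not multivariable MR, so the decomposition uses
unadjusted step effects). The proportion mediated is
$\beta_1\beta_2/\beta$; `decompose_effect()` enforces
`direct + indirect = total` exactly and returns delta-method
uncertainty: $se(\beta_1\beta_2) = \sqrt{\beta_2^2 se_1^2 + \beta_1^2
se_2^2}$ and the analogous three-term expression for the proportion,
treating the three estimates as independent (they come from separate
regressions; the mild positive dependence induced by shared exposure
instruments makes these intervals slightly conservative, which the
package's own coverage checks confirm).

# Estimators

* **IVW** (`mr_ivw()`): weighted regression of $\hat\Gamma$ on
  $\hat\gamma$ through the origin with weights $1/\sigma_\Gamma^2$;
  algebraically the inverse-variance-weighted mean of the Wald ratios.
  The default is the *multiplicative random-effects* form used by the
  standard two-sample-MR tooling: the fixed-effect standard error
  $(\sum w_j \hat\gamma_j^2)^{-1/2}$ is inflated by
  $\max\!\big(1, \sqrt{Q/(J-1)}\big)$, with $Q$ Cochran's heterogeneity
  statistic. The inflation is floored at 1, so the estimator never
  reports less uncertainty than the fixed-effect model; the price is a
  conservative test under perfect homogeneity. For that reason the
  package's null-calibration check (type-I error of the 5% test over
  2,000 simulated null datasets) is run on `mode = "fixed"`, which is
  the exactly calibrated form; `mode = "mre"` lands a little below the
  nominal rate by construction.
* **MR-Egger** (`mr_egger()`): the same weighted regression with a free
  intercept, after orienting all $\hat\gamma_j \ge 0$ (the estimator is
  invariant to joint sign flips). The intercept estimates the average
  *directional* pleiotropic effect of the exposure-increasing alleles;
  the slope is the pleiotropy-adjusted causal estimate. Standard errors
  use the same floored multiplicative inflation, and p-values use a t
  distribution with $J-2$ degrees of freedom (the usual small-sample
  practice for Egger, and the one place the package deviates from plain
  normal p-values).
* **Weighted median** (`mr_weighted_median()`): the ratio value at the
  50% point of the standardized cumulative weights
  $S_j = (\sum_{i\le j} w_i - w_j/2)/\sum w$, linearly interpolated;
  consistent when at least half the weight comes from valid
  instruments. Its standard error is a parametric bootstrap (default
  1,000 draws, seeded): each ratio is resampled from
  $N(\hat\beta_j, se_j)$ and the median recomputed.

# Diagnostics

`sensitivity_report()` bundles Cochran's $Q$ (χ², $J-1$ df), the Egger
intercept test, a leave-one-out IVW table, and MR-PRESSO. The MR-PRESSO
implementation follows the published three-part procedure: a global test
comparing the observed weighted residual sum of squares (residuals taken
against leave-one-out slopes) with its simulated null; a per-variant
simulated tail test, Bonferroni-adjusted, to name outliers; and a
distortion test comparing the estimate shift caused by removing the
named outliers with the shifts caused by removing random subsets of the
same size. Two numerical choices matter:

* empirical p-values use the add-one form $(k+1)/(n_{sim}+1)$, so a
  p-value of exactly zero cannot occur;
* consequently the smallest achievable Bonferroni-adjusted outlier p is
  $J/(n_{sim}+1)$ — with the default $n_{sim} = 1000$ the outlier test
  has resolution down to $J \approx 50$ instruments at the 0.05 level.
  Raise `n_sim` for larger instrument sets.

When no outlier is named, the "corrected" estimate is by construction
the identical IVW object for the full set.

# Instrument processing

Instruments are chosen by strict `p < threshold` (defaults: 1e-5 for
exposures and mediators, where genome-wide hits are scarce for
microbiome and metabolite GWAS; 5e-5 for reverse analyses, which need
more instruments; 5e-8 available). Independence is enforced by greedy
clumping: repeatedly take the smallest-p remaining variant, remove
everything within 10 Mb on the same chromosome with $r^2 \ge 0.001$.
LD is supplied by the caller as a matrix; with no LD available the
package falls back to distance-only clumping (removing everything in
the window) and says so — a deliberately aggressive approximation that
never retains a correlated pair. Ties in p are broken by (chromosome,
position, id) so results cannot depend on row order.

Instrument strength uses $F = R^2(n-k-1)/(k(1-R^2))$ with the per-variant
$R^2_j = 2\,\mathrm{EAF}_j(1-\mathrm{EAF}_j)\beta_j^2$ for a
unit-variance trait, summed over the (independent) instruments;
$F > 10$ is the conventional weak-instrument bar. The per-variant
estimator is the standard choice when genotype-phenotype covariances
are unavailable; both aggregate and per-variant forms are exposed, the
aggregate being the default.

Harmonization matches by variant id, aligns allele pairs directly, by
swap, or after strand complementation, and **removes palindromic (A/T,
C/G) variants by default** — their strand cannot be resolved from
alleles alone. An opt-in `palindromic = "infer"` mode rescues
palindromic variants whose allele frequencies are informative in both
studies (outside the 0.30–0.70 ambiguity band) by matching minor-allele
side; this is a common alternative but stays off by default because
removal is the more fidelity-preserving choice. Unmatched instruments
are dropped, not proxied. The harmonization log partitions the input
exactly (matched + palindromic + incompatible + unmatched = input),
which the tests enforce on every fixture.

# Screening and selection rules

Two-step screening runs at α = 0.05 per step with no multiple-testing
correction by default — the analysed design's own choice; a
Benjamini–Hochberg mode is available (`p_adjust = "BH"` in step 1, the
`fdr` flag in the batch driver adds adjusted columns without changing
the significant set). Mediators whose names match `^X-` (unidentified
metabolites) are excluded at step 2 by default; among the surviving
passers the one with the smallest step-2 p-value is selected. Exposures
whose auxiliary estimators (Egger, weighted median) disagree in sign
with IVW are flagged `direction_consistent = FALSE` but never
auto-excluded — the flag is reported for the analyst to act on, since
the underlying design reports but does not formalize that exclusion. A
wide-CI exclusion was considered and left out: no defensible numeric
threshold exists, and the flag-based reporting covers the same need.

# The synthetic-data generator

`simulate_chain()` emits the three GWAS of a linear chain. Per variant:
MAF $\sim U(0.10, 0.50)$, true exposure effect magnitude
$\sim U(0.10, 0.20)$ with random sign, sampling error
$1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n}$ on a unit-variance trait.
Defaults emulate the consortium regime the package is aimed at:
exposure $n = 18{,}340$ (microbiome-scale), mediator $n = 8{,}299$
(metabolite-scale, with larger per-variant effect magnitudes
$U(0.15, 0.30)$, as metabolite GWAS show), and a binary outcome with
243 cases vs 287,137 controls whose log-odds standard errors follow the
effective sample size $4/(1/\text{cases}+1/\text{controls}) \approx
971$ — reproducing the instability that an extremely case-poor outcome
arm imposes on every downstream estimate. Ten percent of variants get
palindromic allele pairs, and a third of mediator/outcome rows are
reported in the opposite allele orientation, so harmonization is
genuinely exercised. Pleiotropy is injected on the
exposure-increasing-allele scale (`pleiotropy_balanced()`,
`pleiotropy_directional()`, `pleiotropy_outlier()`), matching how the
Egger intercept defines directional pleiotropy. Optional equicorrelated
LD blocks, with their $r^2$ lookup attached, exercise clumping.

`simulate_mediation_study()` scales this to a candidate-mediator panel
(default 50 mediators, 5 true — a desk-scale stand-in for a
1,400-metabolite screen); `simulate_taxa_study()` does the same for a
panel of exposures. What the generator does **not** emulate: realistic
microbiome abundance distributions, polygenic confounding, sample
overlap between the two GWAS, winner's-curse selection at the weak end
(instrument magnitudes are drawn comfortably above the selection
threshold), or realistic LD beyond block-equicorrelation. Passing the
package's recovery tests therefore demonstrates correctness of the
estimators and plumbing under the assumed model, not robustness to
every pathology of real consortium data.

# Validation problem sizes

The shipped checks use: 2,000 null chains of 30 instruments for IVW
calibration; 100 replicates for the 10-σ MR-PRESSO outlier detection
rate; 200 replicates of the full select → clump → harmonize → IVW →
screen → decompose pipeline with 50 candidate mediators and 50
instruments per trait (β₁ = 0.3, β₂ = 0.5, direct = 0.2, so the true
proportion mediated is 3/7 ≈ 0.4286) — sizes chosen to make
coverage and detection rates estimable to a few percent while keeping a
full run in the order of a minute.

# Known limitations

* No multivariable MR, mode-based estimators, Steiger filtering,
  Radial-MR or contamination-mixture methods.
* No proxy-variant lookup or genome-build liftover; harmonization
  assumes shared rsIDs and biallelic SNPs.
* Distance-only clumping (the no-LD fallback) can discard independent
  variants that merely sit close together.
* The delta-method proportion interval assumes independence of the
  three estimates and approximate normality of a ratio; with a weak
  total effect ($\beta$ near 0) the proportion is unstable and its
  interval unreliable — the package flags $\beta = 0$ but cannot
  rescue near-zero totals.
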