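---
title: "Two-sample Mendelian randomization with mrlite: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrlite: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrlite)
```

## The design and its assumptions

Two-sample Mendelian randomization treats genetic variants as
instrumental variables for an exposure: the variant–exposure
associations come from one GWAS, the variant–outcome associations from
another, and a causal effect is inferred from the ratio of the two.
Three conditions must hold for a variant to be a valid instrument: it is
associated with the exposure (relevance), it shares no common cause with
the outcome (independence), and it affects the outcome only through the
exposure (no horizontal pleiotropy). The package's three estimators
relax the third condition to different degrees, which is why they are
reported together:

* **IVW** assumes every instrument is valid (or that pleiotropy is
  balanced with mean zero). It is the most efficient estimator and the
  main analysis.
* **The weighted median** is consistent when at least half of the
  instrument *weight* comes from valid instruments.
* **MR-Egger** tolerates pleiotropy in every instrument provided the
  pleiotropic effects are uncorrelated with instrument strength (the
  InSIDE condition); the price is much lower precision. Its intercept
  is itself a diagnostic: a nonzero value indicates average directional
  pleiotropy.

The bundled instrument set (`ltl_constipation()`) carries 15 SNPs for
leukocyte telomere length (exposure GWAS of 78,592 Europeans) against
constipation (FinnGen, 26,919 cases / 282,235 controls), already
harmonized to a common effect-allele orientation.

## Harmonization

`harmonize()` aligns the outcome table to the exposure's effect-allele
orientation over the SNPs present in both tables. Identical allele
pairs pass through; swapped pairs flip the sign of the outcome beta
(and complement the effect-allele frequency); anything else is dropped
as incompatible. Palindromic SNPs (A/T, C/G) cannot be resolved by
allele labels alone, so a policy decides:

* `"drop"` (default) — remove them; conservative standard practice, and
  the only safe option when allele frequencies are unavailable.
* `"infer_by_eaf"` — keep a palindromic SNP when both effect-allele
  frequencies are outside `0.5 ± w` (default window `w = 0.08`) and
  orient by frequency agreement; SNPs inside the window, or with a
  missing frequency, fall back to dropping.
* `"keep"` — trust the written orientation. This exists for input that
  is *already* harmonized, such as a published instrument table; the
  bundled LTL set contains four palindromic SNPs whose orientation the
  publication already resolved, and reloading it must be a no-op.

Every decision is tagged per SNP (`kept-as-is`, `outcome-flipped`,
`dropped-palindromic`, `dropped-incompatible`) and appended to a
line-oriented audit log, so retained + removed always accounts for every
input SNP. Rows are sorted by SNP identifier before estimation, making
all downstream output deterministic in the input order.

## Instrument selection

`filter_instruments()` applies the usual two-sample screens with strict
inequalities: exposure association `p < 5e-8` and outcome association
`p > 5e-8` (both configurable), plus a user-supplied exclusion list —
the hook for variants flagged by curated phenotype lookups as acting
through confounding pathways. True LD clumping needs a genotype
reference panel, which the package deliberately does not depend on;
`prune_by_distance()` instead ranks SNPs by exposure p-value and greedily
enforces a minimum same-chromosome spacing (default 10,000 kb, the usual
clumping window), honoring a user-supplied pairwise LD table with
`r² < 0.001` when one is available. Pre-clumped input simply skips this
stage.

Instrument strength is summarized by
`R² = Σ 2 MAF(1−MAF) β²` (variance explained, standardized exposure) and
`F = R²/(1−R²) · (n−k−1)/k`; values of `F` below 10 trigger a
weak-instrument warning. The bundled table does not print MAFs, so its
published `F` (≈ 200) can only be checked by formula inversion, not
recomputed — the acceptance material therefore excludes it.

## Estimation: numerical choices

*Wald ratio standard errors.* The first-order delta method
(`SE_Y/|β_X|`) is the default everywhere — weights, Cochran's Q, and the
funnel plot — matching common practice; the second-order form adding the
exposure-side term is available via `se_order = "second"` and is never
smaller.

*IVW.* The fixed-effect standard error is `sqrt(1/Σw)`. The default
random-effects model is multiplicative with a floor:
`SE = SE_fixed · max(1, sqrt(Q/(k−1)))`. The floor means heterogeneity
can only widen intervals; with one instrument only the fixed-effect
model is defined, and it then reproduces the Wald ratio and its SE
exactly. P-values are two-sided normal; intervals use
`z = qnorm(0.975) = 1.959964` on the log-odds scale and are exponentiated
for reporting.

*MR-Egger.* Each SNP is first oriented so its exposure beta is positive
— without this the intercept is not identified, because flipping a
SNP's reported allele flips both betas and would change the fit.
Standard errors carry the weighted-regression residual scaling
`sqrt(RSS/(k−2))` with no floor, and tests use `t` with `k−2` degrees of
freedom. A design with all exposure betas identical is singular and
rejected.

*Weighted median.* Ratios are sorted (ties broken by SNP identifier for
determinism), weights normalized, and the estimate is the linear
interpolation of the cumulative-midpoint function at one half. The
standard error is a parametric bootstrap (default 1,000 iterations):
betas are resampled from normal distributions centered on their observed
values with their reported SEs, and weights are recomputed per resample.
The bootstrap seed is part of the configuration (default 20230913) so
reported SEs are reproducible; across seeds the SE varies by a few
thousandths at 1,000 iterations.

*MR-PRESSO.* The observed statistic is the weighted residual sum of
squares against leave-one-out IVW predictions; its null distribution is
simulated (default 1,000 iterations, seeded). The empirical p-value uses
the `(1 + #exceed)/(n_sim + 1)` estimator, so it is never exactly zero
and is bounded below by `1/(n_sim+1)`. Per-SNP outlier p-values are
Bonferroni-adjusted across the `k` instruments and flagged below 0.05;
the distortion test is not implemented. At least four instruments are
required — below that the leave-one-out null model is too small to be
meaningful.

*Pipeline seeds.* `run_mr()` takes one top-level seed and derives the
weighted-median and MR-PRESSO sub-seeds from it by fixed offsets, so a
configuration file fully determines the report (timestamps aside).

## What the printed fixture can and cannot reproduce

The packaged instrument table prints betas and standard errors to three
decimals. Quantities that are smooth first-order functions of the table
(the IVW odds ratio and SE, the Egger slope and SE) agree with the
published three-decimal values essentially exactly. Quantities that
*amplify* rounding do not: the weighted median interpolates between two
adjacent ratios whose numerators are printed at ±0.0005 on values of
order 0.01, and chi-square tail probabilities move visibly when Q shifts
by a fraction of a unit.

The package quantifies this by uncertainty propagation: perturb every
printed cell by an independent `U(−0.0005, +0.0005)` draw (the rounding
width) and recompute each statistic a few hundred times:

```{r rounding-envelope, eval = FALSE}
h <- ltl_constipation()
perturb <- function(h) {
  for (col in c("beta_exposure", "se_exposure", "beta_outcome",
                "se_outcome")) {
    h[[col]] <- h[[col]] + runif(nrow(h), -5e-4, 5e-4)
  }
  h
}
set.seed(1)
envelope <- replicate(600, {
  hp <- perturb(h)
  c(ivw = mr_ivw(hp)$or_, q_p = cochran_q(hp)$pval,
    wm = mr_weighted_median(hp, n_boot = 1, seed = 1)$or_)
})
apply(envelope, 1, quantile, c(0.005, 0.995))
```

The acceptance tests compare recomputed values to the published ones at
the half-width of this envelope (floored at one unit in the last printed
digit); the envelope half-widths are the tolerances hard-coded there.
One published value falls outside any such envelope: the MR-PRESSO
global p-value. From the printed table the observed residual statistic
is ≈ 23, while the published p would require ≈ 14 — a gap rounding
cannot produce, so that p-value was evidently computed from
full-precision (or differently filtered) data. The corresponding
acceptance assertion is expected to fail until a full-precision table is
available; the qualitative conclusion it supports (no heterogeneity,
p > 0.05, no outliers) reproduces cleanly.

## The synthetic-data generator

`mr_scenario()` + `simulate()` generate two-sample summary statistics
directly — no individual-level genotypes — which is exactly the
information the estimators consume. Per SNP: MAF uniform on
`maf_range` (default 0.1–0.5); true exposure effect magnitude uniform on
`beta_x_range` (default 0.03–0.09 SD per allele, the range of the
bundled instruments) with random sign; sampling SEs from the
standardized-trait approximation `1/sqrt(2·MAF(1−MAF)·n)`; observed
betas normal around their generating means; the outcome mean is
`θ·β_X + α` with pleiotropy `α` per regime — zero, balanced
`N(0, sd²)`, or directional `N(mean, sd²)` expressed in the
exposure-increasing orientation so that InSIDE holds by construction.
Default sample sizes (78,592 / 309,154) mirror the bundled study's
shape. The truth record carries `θ`, the true betas, `α`, validity
flags and MAFs, so every observed quantity's generating distribution is
recomputable.

What the generator does *not* emulate: LD between instruments, sample
overlap between the two GWAS, winner's-curse selection of instruments,
and the binomial sampling structure of a binary outcome (its SEs use the
same standardized approximation, with the scale absorbed into θ).
Calibration results on these synthetic scenarios therefore validate the
estimators' arithmetic and their behavior under the stated violation
models — not robustness to LD, overlap, or selection effects in real
data.

`run_scenario_grid()` summarizes bias, RMSE, 95%-interval coverage and
rejection rates per method over replicated draws, with per-replicate
seeds derived from a base seed by a fixed counter. The test suite uses
it at problem sizes chosen to keep Monte-Carlo error small but the run
short: 2,000 replicates of a 50-instrument null scenario for type-I
error and coverage (binomial SE ≈ 0.005), 2,000 replicates for the
balanced-pleiotropy size of the Egger intercept test, and 500 replicates
of a directional-pleiotropy scenario — with the pleiotropic mean sized
for ≈ 95% planned power of the intercept test — for the Egger-vs-IVW
bias ordering.

## Known limitations

* No reference-panel LD computation, PhenoScanner-style confounder
  lookup, liftover, or multi-allelic support; pruning is positional.
* No mode-based, robust-adjusted-profile-score, or multivariable
  estimators, and no Steiger directionality filtering.
* Egger inference is not NOME-corrected (no I² diagnostic or SIMEX).
* Binary-outcome effects are treated on the log-odds scale throughout;
  no liability-scale conversion.
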