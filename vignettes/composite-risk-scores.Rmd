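---
title: "Composite risk scores: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite risk scores: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crscore)
```

## The model

`crscore` implements a sex-stratified composite risk score for a binary
disease outcome. The central device is the *prevalence-scale risk
transform*: instead of modelling a measure's effect parametrically, every
measure is replaced by the empirical disease prevalence among training-set
individuals with similar values.

* A continuous measure (raw polygenic score, BMI, birth weight) is sorted
  and split into `n_bins = 100` equal-size percentile bins; the risk of a
  bin is its case fraction (`fit_quantile_bins()`).
* A categorical measure (comparative body size at age ten: thinner /
  average / plumper) gets one bin per label (`fit_categorical_bins()`).
* Age gets one bin per rounded year (`fit_age_bins()`).

This has two consequences worth making explicit. First, non-monotone
relationships — birth weight's U shape, where *low* birth weight carries
the strongest risk and high birth weight a weaker excess — need no special
handling: each bin simply reports what was observed. Second, all
components end up on the same scale (a probability), so they can be
combined with weights without prior normalization.

The composite score is the convex combination
$$CRS_i = \alpha\,GR_i + \beta\,PR_i + \gamma\,AR_i, \qquad
\alpha+\beta+\gamma = 1,\ \alpha,\beta,\gamma \ge 0,$$
with 2-component variants (PRS-with-age $\alpha GR_i + \gamma AR_i$,
measure-with-age $\beta PR_i + \gamma AR_i$) and the degenerate age-alone
measure $AR_i$. Weights are fitted by *exhaustive* enumeration of the
simplex lattice in steps of 0.025 (`enumerate_weights()`: 41 vectors for
two components, 861 for three), picking the vector with maximal training
ROC AUC. Evaluation uses per-percentile odds ratios on the held-out data,
aggregated over repeated random 70/30 splits (`repeat_experiment()`), and
paired Wilcoxon signed-rank tests between measures fitted on shared splits.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_bins` | 100 | percentile bins for risk transforms and OR profiles |
| `step` | 0.025 | weight-grid lattice step (861 grid points for 3 components) |
| `train_fraction` | 0.7 | share of individuals used for fitting |
| `n_repetitions` | 1000 | random splits for OR means/SDs |
| `age_range` | 40–70 | inclusive inclusion bounds, years |

The defaults are the protocol constants of the analysis the package
implements; change them only to explore, not to compare against the
reference pattern.

## Numerical choices

* **AUC** is the tie-aware rank statistic (probability a random case
  outscores a random control, ties ½), computed on the *continuous*
  composite score. A percentile-binned variant (`roc_auc_binned()`) exists
  for figure-style displays, but fitting uses the continuous version: it is
  strictly more informative and identical in expectation. The grid search
  is the hot loop (861 AUCs per repetition) and is implemented in C++ on
  case/control counts of unique risk-value rows; equal scores compare
  exactly equal, so AUC ties are exact and the tie-break — first maximal
  vector in enumeration order (first component major, descending) — is
  deterministic.
* **Quantile ties.** Percentile binning must produce equal-size bins even
  on heavily tied inputs (composite scores take at most a few thousand
  distinct values). Individuals are ranked by (value, seeded uniform
  tie-break) and cut into contiguous rank blocks; the tie-break seed is an
  argument and is recorded in the fitted model, so fits are reproducible.
* **Test-set assignment** uses training-derived lower bin edges as
  half-open intervals, the last interval closed above; out-of-range values
  clamp to the extreme bins. Age years unseen in training map to the
  nearest observed year, ties to the younger year (the bounded 40–70 range
  keeps gaps small). Categorical labels unseen in training are an error.
* **Zero cells.** A percentile with no cases (or no controls) has an
  undefined odds ratio; it is excluded from means and SDs, and the count of
  defined repetitions is reported per percentile. No continuity correction
  is applied by default — corrections would bias the mean — but a
  Haldane–Anscombe `+0.5` mode is available by flag. Bins with zero cases
  get risk 0 with no smoothing; at the cohort sizes the method targets this
  is rare, but it is a real limitation for small strata.
* **Wilcoxon signed-rank.** Zero differences are excluded; for up to 25
  remaining pairs the exact null distribution of the positive-rank sum is
  computed by dynamic programming over doubled midranks (equivalent to
  enumerating all $2^n$ sign assignments, and valid under ties); above 25 a
  tie-corrected normal approximation without continuity correction is used.
  P-values below 1e-300 are reported with an underflow-safe label. The
  repeated-splits design makes the paired samples *dependent* (test sets
  overlap across repetitions); the test is computed as the protocol
  prescribes, but its p-values should be read as descriptive strength of
  a paired difference, not as if the 1000 repetitions were independent.
* **Determinism.** Every random draw flows through a seed argument; each
  repetition derives a sub-seed from the master seed, so results are
  independent of execution order, and rerunning a pipeline config yields
  byte-identical outputs.

## What the synthetic cohorts emulate — and what they don't

The generator (`simulation_config()` / `generate_cohort()`) draws disease
status from a logistic liability model whose terms encode the qualitative
structure the analysis assumes: higher baseline prevalence in males
(defaults 0.06 vs 0.04, mid-age rate at the covariate means), a monotone
raw-PRS effect, a monotone (log-)BMI effect, a birth-weight term
$\beta_1 z + \beta_2 z^2$ with $\beta_1 < 0 < \beta_2$ giving the
low-weight-dominant U shape, category offsets with plumper > thinner >
average, and a linear age trend over 40–70 centred at 55. Marginals are
stand-ins chosen once for plausibility — standard-normal PRS, birth weight
$\mathcal N(3.3, 0.5^2)$ kg, lognormal BMI with median ≈ 27 kg/m² and
log-SD 0.15, body-size probabilities (0.3, 0.5, 0.2) — and are
config-overridable; only directions and monotonicity matter for the tests.
Defaults for the effect sizes (β_prs 0.4, β_bmi 0.8, birth weight −0.3 /
+0.15, body size +0.15/0/+0.4, β_age 0.04/yr) were picked once so that the
simulated percentile-OR and AUC patterns sit in the reference analysis's
qualitative regime (BMI stronger than PRS, both clearly predictive, age
weakest).

Not emulated: linkage disequilibrium or any genetic architecture behind
the PRS (genotypes are independent binomials; `generate_genotypes()`
exists to round-trip the scoring arithmetic, not to simulate genetics),
real relatedness (kinship groups are labels only), ancestry structure,
measurement error in self-reported phenotypes, and the marginal
distributions of a real biobank. A green test therefore establishes that
the *pipeline machinery* is correct and that the method recovers stated
qualitative structure — not that the package reproduces any particular
cohort's numbers.

Acceptance simulations use single-sex cohorts (`sex_ratio = 0`): the
protocol is sex-stratified throughout, so running one sex lets the full
stated n enter one fit instead of being halved. This was fixed a priori.

## Design choices where the design was open

* **In-sample weight fitting, and why "weight recovery" fails.** The
  protocol learns both the bin risks and the simplex weights on the same
  training split. A consequence we quantified: a bin's risk is its own
  in-sample case fraction, so even a pure-noise component acquires
  *in-sample* discrimination (at 35,000 training rows, 100 bins and 5%
  prevalence, bin-risk sampling noise is ~23% of prevalence, worth ≈ 0.06
  of training AUC), and the grid search rationally assigns it weight
  (≈ 0.3) even though its held-out AUC is 0.5. One acceptance property
  expecting the informative component to keep ≥ 0.8 of the weight in that
  setting is therefore left failing by design: making it pass would
  require departing from the stated protocol (e.g. out-of-fold risk
  estimation), which we chose not to do. At real-biobank scale (~2,000
  members per bin) the same effect exists but is ~2.4× smaller per bin
  risk.
* **Kinship dedup** keeps the lexicographically lowest id per same-sex
  kinship group — any deterministic rule works; this one needs no RNG.
* **Age-range bounds** 40–70 are read inclusively.
* **Repeated phenotype measurements** supplied as multiple columns are
  collapsed to their maximum, matching the ingestion convention of the
  reference analysis.
* **Birth-weight coefficients.** With the default (−0.3, +0.15), the logit
  offset $-0.3z + 0.15z^2$ has roots at $z = 0$ and $z = 2$: prevalence at
  two SDs *above* the mean equals baseline exactly, and the expected
  elevation of the top 5 birth-weight percentiles over the middle is only
  ~0.04 logits — detectable at n = 100,000 only with ~0.6 SE of margin.
  Tests assert what the polynomial actually implies rather than a strict
  inequality it does not.

## Known limitations

* No confidence intervals from analytic OR formulas — uncertainty is the
  SD over repetitions, as in the reference protocol.
* No multiple-testing correction across the 100 percentile comparisons.
* No VCF/BGEN ingestion, genotype QC, imputation or weight estimation:
  the cohort table and the three-column scoring file are the boundaries.
* Zero-case bins get risk 0; with very small strata the transform is
  noisy and unsmoothed.
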