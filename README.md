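# crscore

Composite risk scores (CRS) combining a polygenic risk score with
phenotypic measures and age, for sex-stratified prediction of a binary
disease outcome such as type 2 diabetes (T2D).

## Who this is for

Statistical geneticists and epidemiologists who want to ask: *does adding a
clinical or early-life phenotype (BMI, birth weight, childhood body size)
to a polygenic risk score improve disease risk stratification?* The package
provides the full analysis pipeline — prevalence-scale risk transforms,
simplex weight fitting, repeated train/test evaluation — plus a seeded
synthetic cohort generator so every stage is testable without access to
restricted biobank data.

## The method

Each measure is first converted to an empirical **risk**: training-set
individuals are sorted by the measure and split into 100 equal-size
percentile bins (or one bin per category / per year of age), and the risk
of a bin is its observed disease prevalence — if 5% of a bin's members are
cases, every member of that bin has risk 0.05. This yields a genetic risk
GR (from the raw PRS = Σᵢ wᵢGᵢ over allele dosages Gᵢ ∈ {0,1,2}), a
phenotypic risk PR, and an age risk AR, all on the common prevalence scale,
with no monotonicity assumption (birth weight's U-shaped effect is handled
for free).

The composite risk score of individual *i* is the convex combination

```
CRSᵢ = α·GRᵢ + β·PRᵢ + γ·ARᵢ ,   α + β + γ = 1,  α, β, γ ≥ 0
```

with (α, β, γ) chosen by exhaustive grid search in steps of 0.025 to
maximize the ROC AUC (rank statistic) on a 70% training split. Evaluation
on the held-out 30% uses per-percentile odds ratios,
`OR(p) = (Dₚ/Hₚ) / (D₋ₚ/H₋ₚ)`, averaged over (by default) 1000 random
splits; measures are fitted on shared splits, so they can be compared with
a paired Wilcoxon signed-rank test. Everything is run separately per sex.

## Worked example

```r
library(crscore)

cfg    <- simulation_config(n_individuals = 20000, sex_ratio = 0, seed = 7)
cohort <- apply_cohort_filters(generate_cohort(cfg))

res <- repeat_experiment(
  cohort,
  measures = list(crs = c("prs", "bmi", "age"), prs = c("prs", "age"),
                  bmi = c("bmi", "age"), age = "age"),
  n_repetitions = 50, seed = 7)
res
#> <repeat_result: 50 repetitions, 4 measures (crs, prs, bmi, age), 100 bins>
#>   crs            mean test AUC 0.7171, top-percentile mean OR 7.620
#>   prs            mean test AUC 0.6121, top-percentile mean OR 2.489
#>   bmi            mean test AUC 0.7050, top-percentile mean OR 5.923
#>   age            mean test AUC 0.5808, top-percentile mean OR 1.385

round(colMeans(res$measures$crs$weights), 3)
#>   prs   bmi   age
#> 0.319 0.347 0.334

compare_measures(res, "crs", "bmi")$auc_test$p.label
#> [1] "7.556929e-10"
```

Reading the output: the composite score dominates each of its components —
a mean held-out AUC of 0.717 vs 0.705 (BMI + age) and 0.612 (PRS + age),
and individuals in its top score percentile have 7.6-fold disease odds
relative to everyone else, vs 5.9-fold for the BMI measure and 2.5-fold for
the PRS measure. The paired signed-rank p-value (~8·10⁻¹⁰ over 50 shared
splits) confirms the AUC gain of CRS over its best single component.

The same analysis is available from the command line (`exec/crscore`):

```sh
crscore simulate --config sim.json --out cohort.tsv
crscore score    --weights w.tsv --dosages g.tsv --out prs.tsv
crscore evaluate --cohort cohort.tsv --measure crs:prs+bmi+age \
                 --measure age:age --reps 1000 --seed 17 --sex female --out results/
crscore run      --config run.json
```

## Layout

- `R/` — cohort simulation, PRS scoring, risk transforms, weight fitting,
  evaluation, pipeline/CLI
- `src/` — the grid-search AUC hot loop (Rcpp)
- `vignettes/composite-risk-scores.Rmd` — the model, its assumptions,
  parameter choices, and known limitations
- `tests/testthat/` — unit, property and acceptance suites
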