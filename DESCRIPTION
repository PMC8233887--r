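Package: crscore
Title: Composite Risk Scores Combining Polygenic and Phenotypic Disease Risk
Version: 0.1.0
Authors@R:
    person("crscore", "maintainers", email = "crscore@example.org", role = c("aut", "cre"))
Description: Builds sex-stratified composite risk scores (CRS) for a binary
    disease outcome by converting a raw polygenic risk score, continuous or
    categorical phenotypes (e.g. BMI, birth weight, childhood body size) and
    age into empirical disease-prevalence risks learned on a training set,
    combining them with nonnegative simplex weights fitted by exhaustive
    grid search maximizing the ROC AUC, and evaluating any score on held-out
    data via per-percentile odds ratios aggregated over repeated random
    train/test splits.  Includes a seeded synthetic cohort generator with a
    logistic liability model (monotone polygenic and BMI effects, a U-shaped
    birth-weight effect, categorical childhood body size, age trend and
    sex-specific baseline prevalence), allele-dosage scoring from a marker
    weight table, a paired Wilcoxon signed-rank test with exact small-sample
    p-values, and a configuration-driven command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
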