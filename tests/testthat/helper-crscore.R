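# Shared fixture builders; everything is generated in code at test time.

# Cohort with a single configurable effect, all others switched off.
null_config <- function(n, seed, base = 0.05, ...) {
  simulation_config(
    n_individuals = n, sex_ratio = 0,
    base_prevalence_male = base, base_prevalence_female = base,
    beta_prs = 0, beta_bmi = 0, beta_bw_linear = 0, beta_bw_quad = 0,
    bodysize_logodds = c(thinner = 0, average = 0, plumper = 0),
    beta_age = 0, seed = seed, ...)
}

# Small random score/label sets for OR and AUC oracles.
random_labelled_scores <- function(n, prevalence, seed) {
  with_seed <- get("with_seed", asNamespace("crscore"))
  with_seed(seed, list(scores = runif(n),
                       labels = rbinom(n, 1L, prevalence)))
}

# Independent O(n^2) pairwise AUC oracle (probability a random case
# outscores a random control, ties counted one half).
pairwise_auc_oracle <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  tot <- 0
  for (x in cs) tot <- tot + sum(x > ct) + 0.5 * sum(x == ct)
  tot / (length(cs) * length(ct))
}
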