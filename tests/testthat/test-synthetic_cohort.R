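test_that("configuration is validated", {
  expect_error(simulation_config(n_individuals = 100), "200")
  expect_error(simulation_config(500, base_prevalence_male = 0), "prevalences")
  expect_error(simulation_config(500, base_prevalence_female = 1), "prevalences")
  expect_error(simulation_config(500, age_range = c(35, 70)), "age_range")
  expect_error(simulation_config(500, age_range = c(60, 50)), "age_range")
  expect_error(simulation_config(500, allele_freq_range = c(0, 0.5)), "allele_freq")
  expect_error(simulation_config(500, bodysize_logodds = c(a = 1)), "bodysize")
})

test_that("the same config and seed give a byte-identical cohort", {
  cfg <- simulation_config(1000, seed = 77, kinship_rate = 0.1)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(simulation_config(1000, seed = 78,
                                                              kinship_rate = 0.1))))
  # generation does not disturb the session RNG
  set.seed(1); before <- runif(3)
  invisible(generate_cohort(cfg))
  set.seed(1); expect_identical(before, runif(3))
})

test_that("cohort table obeys its invariants", {
  cfg <- simulation_config(5000, seed = 3, kinship_rate = 0.2,
                           age_range = c(45L, 65L))
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh), 5000)
  expect_false(anyDuplicated(coh$id) > 0)
  expect_true(all(coh$t2d %in% 0:1))
  expect_true(all(coh$age >= 45 & coh$age <= 65))
  expect_true(all(coh$body_size_age10 %in% c("thinner", "average", "plumper")))
  expect_true(all(coh$sex %in% c("female", "male")))
  kin <- table(coh$kinship_group)
  expect_true(all(kin == 2))
})

test_that("null model recovers the base prevalence (sex-stratified, 4 SE)", {
  cfg <- simulation_config(
    100000, sex_ratio = 0.5,
    base_prevalence_male = 0.06, base_prevalence_female = 0.04,
    beta_prs = 0, beta_bmi = 0, beta_bw_linear = 0, beta_bw_quad = 0,
    bodysize_logodds = c(thinner = 0, average = 0, plumper = 0),
    beta_age = 0, seed = 42)
  coh <- generate_cohort(cfg)
  for (sx in c("female", "male")) {
    sub <- coh[coh$sex == sx, ]
    p0 <- if (sx == "female") 0.04 else 0.06
    se <- sqrt(p0 * (1 - p0) / nrow(sub))
    expect_lt(abs(mean(sub$t2d) - p0), 4 * se)
  }
  # overall prevalence at 0.05 base within the stated 0.003 band
  coh2 <- generate_cohort(null_config(100000, seed = 42))
  expect_lt(abs(mean(coh2$t2d) - 0.05), 0.003)
})

test_that("PRS effect matches the quadrature oracle decile by decile", {
  beta <- 0.5; base <- 0.05
  cfg <- null_config(100000, seed = 42)
  cfg$beta_prs <- beta
  coh <- generate_cohort(cfg)
  # closed-form expectation: E[plogis(qlogis(base) + beta z) | z in decile]
  dec_prev <- function(k) {
    lo <- qnorm((k - 1) / 10); hi <- qnorm(k / 10)
    stats::integrate(function(z) plogis(qlogis(base) + beta * z) * dnorm(z),
                     lo, hi)$value / (pnorm(hi) - pnorm(lo))
  }
  dec <- cut(coh$raw_prs, qnorm(0:10 / 10), labels = FALSE)
  obs <- tapply(coh$t2d, dec, mean)
  n_k <- tabulate(dec, 10)
  for (k in 1:10) {
    exp_k <- dec_prev(k)
    se <- sqrt(exp_k * (1 - exp_k) / n_k[k])
    expect_lt(abs(obs[[k]] - exp_k), 5 * se)
  }
  expect_gt(obs[[10]], obs[[1]])
})

test_that("birth-weight U shape follows the logit polynomial oracle", {
  cfg <- null_config(100000, seed = 42)
  cfg$beta_bw_linear <- -0.3; cfg$beta_bw_quad <- 0.15
  poly_prev <- function(z) plogis(qlogis(0.05) - 0.3 * z + 0.15 * z^2)
  # the stated oracle itself: low weight dominates; the polynomial is exactly
  # zero at both z = 0 and z = +2, so those two prevalences are equal
  expect_gt(poly_prev(-2), poly_prev(2))
  expect_gt(poly_prev(-2), poly_prev(0))
  expect_equal(poly_prev(2), poly_prev(0))
  coh <- generate_cohort(cfg)
  z <- (coh$birth_weight - 3.3) / 0.5
  p_at <- function(z0) mean(coh$t2d[abs(z - z0) < 0.25])
  expect_gt(p_at(-2), p_at(2))
  expect_gt(p_at(-2), p_at(0))
})

test_that("each remaining effect produces its stated prevalence gradient", {
  mk <- function(field, value) {
    cfg <- null_config(100000, seed = 42)
    cfg[[field]] <- value
    generate_cohort(cfg)
  }
  bmi <- mk("beta_bmi", 0.5)
  q <- quantile(bmi$bmi, c(0.1, 0.9))
  expect_gt(mean(bmi$t2d[bmi$bmi >= q[2]]), mean(bmi$t2d[bmi$bmi <= q[1]]))

  age <- mk("beta_age", 0.05)
  expect_gt(mean(age$t2d[age$age >= 65]), mean(age$t2d[age$age <= 45]))

  bs <- mk("bodysize_logodds", c(thinner = 0.15, average = 0, plumper = 0.4))
  prev <- tapply(bs$t2d, bs$body_size_age10, mean)
  expect_gt(prev[["plumper"]], prev[["thinner"]])
  expect_gt(prev[["thinner"]], prev[["average"]])
})

test_that("genotype generation round-trips through compute_raw_prs exactly", {
  cfg <- simulation_config(300, n_markers = 50, seed = 9)
  g <- generate_genotypes(cfg)
  expect_true(all(g$dosages %in% 0:2))
  expect_identical(generate_genotypes(cfg), g)
  scored <- compute_raw_prs(g$dosages, g$weights)
  expect_identical(scored$raw_prs, unname(g$raw_prs))
  # single marker, weight forced to 1: implied score is the dosage itself
  cfg1 <- simulation_config(200, n_markers = 1, seed = 5)
  g1 <- generate_genotypes(cfg1)
  w1 <- g1$weights; w1$weight <- 1
  expect_equal(compute_raw_prs(g1$dosages, w1)$raw_prs,
               as.numeric(g1$dosages[, 1]))
})

test_that("score variance matches the independent-binomial formula", {
  cfg <- simulation_config(2000, n_markers = 1000,
                           allele_freq_range = c(0.5, 0.5), seed = 21)
  g <- generate_genotypes(cfg)
  expected <- sum(g$weights$weight^2) * 2 * 0.5 * 0.5
  expect_lt(abs(var(g$raw_prs) / expected - 1), 0.1)
})

test_that("cohort tsv round trip preserves the table", {
  coh <- generate_cohort(simulation_config(300, seed = 2, kinship_rate = 0.1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$id, coh$id)
  expect_equal(back$raw_prs, coh$raw_prs, tolerance = 1e-12)
  expect_identical(back$t2d, coh$t2d)
  expect_identical(back$kinship_group, coh$kinship_group)
  expect_identical(names(back), names(coh))
})
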