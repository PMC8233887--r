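test_that("percentile OR reproduces the 2x2 arithmetic example", {
  # top bin: 10 cases / 90 controls; elsewhere: 100 cases / 9900 controls
  # OR = (10/90) / (100/9900) = 11.0
  n <- 10100
  scores <- c(runif(10000), runif(100, 2, 3))
  labels <- c(rep(1, 100), rep(0, 9900), rep(1, 10), rep(0, 90))
  res <- odds_ratio_percentiles(scores, labels, n_bins = 101)
  expect_equal(res$D[101], 10)
  expect_equal(res$H[101], 90)
  expect_equal(res$or[101], 11.0)
  expect_equal(attr(res, "total_cases"), 110)
  expect_equal(attr(res, "total_controls"), 9990)
})

test_that("homogeneous percentiles all have OR 1", {
  scores <- seq_len(10000)
  labels <- rep(c(rep(0, 50), 1, rep(0, 49)), 100)  # 1 case per bin of 100
  res <- odds_ratio_percentiles(scores, labels)
  expect_equal(res$D, rep(1, 100))
  expect_equal(res$or, rep(1, 100))
})

test_that("percentile ORs equal a brute-force contingency oracle", {
  for (s in 1:3) {
    rl <- random_labelled_scores(2000, 0.15, seed = 100 + s)
    res <- odds_ratio_percentiles(rl$scores, rl$labels, tiebreak_seed = s)
    # independent oracle: sort, split into consecutive blocks of 20,
    # build each 2x2 table explicitly
    ord <- order(rl$scores)  # scores are continuous: no ties
    y <- rl$labels[ord]
    for (p in 1:100) {
      members <- y[(20 * (p - 1) + 1):(20 * p)]
      a <- sum(members); b <- 20 - a
      cc <- sum(y) - a; d <- (2000 - sum(y)) - b
      oracle <- if (a == 0 || b == 0 || cc == 0 || d == 0) NA_real_
                else (a / b) / (cc / d)
      expect_equal(res$or[p], oracle, tolerance = 0)
    }
    expect_equal(sum(res$D), sum(rl$labels))
  }
})

test_that("haldane mode defines every OR via +0.5 cells", {
  scores <- seq_len(300)
  labels <- c(rep(0, 290), rep(1, 10))  # cases all in the top bins
  res <- odds_ratio_percentiles(scores, labels, n_bins = 30, haldane = TRUE)
  expect_false(anyNA(res$or))
  p1 <- res[1, ]  # bottom bin: 0 cases, 10 controls
  expect_equal(p1$or, ((0 + 0.5) / (10 + 0.5)) / ((10 + 0.5) / (280 + 0.5)))
  res0 <- odds_ratio_percentiles(scores, labels, n_bins = 30)
  expect_true(is.na(res0$or[1]))
})

test_that("OR profile preconditions are enforced", {
  expect_error(odds_ratio_percentiles(runif(50), rbinom(50, 1, 0.5)), "fewer")
  expect_error(odds_ratio_percentiles(runif(200), rep(0, 200)), "both classes")
})

test_that("wilcoxon signed rank: identity, exactness, large shifts", {
  expect_warning(res <- wilcoxon_signed_rank(1:12, 1:12), "zero")
  expect_equal(res$p.value, 1)

  # exact small-sample path against brute force over all 2^12 assignments
  set.seed(50)
  a <- rnorm(12); b <- rnorm(12)
  got <- wilcoxon_signed_rank(a, b)
  d <- a - b; r <- rank(abs(d)); W <- sum(r[d > 0]); n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- signs %*% r
  p_oracle <- min(1, 2 * min(mean(Ws <= W), mean(Ws >= W)))
  expect_equal(got$statistic, W)
  expect_equal(got$p.value, p_oracle, tolerance = 1e-12)
  expect_identical(got$method, "exact")

  # agreement with stats::wilcox.test on both paths (distinct untied data)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
  set.seed(51)
  a2 <- rnorm(100); b2 <- rnorm(100, -0.3)
  got2 <- wilcoxon_signed_rank(a2, b2)
  ref2 <- stats::wilcox.test(a2, b2, paired = TRUE, exact = FALSE,
                             correct = FALSE)
  expect_equal(got2$p.value, ref2$p.value, tolerance = 1e-12)

  # a stochastically dominant over b: p reported with an underflow-safe label
  set.seed(52)
  a3 <- rnorm(1000, 5); b3 <- rnorm(1000)
  got3 <- wilcoxon_signed_rank(a3, b3)
  expect_lt(got3$p.value, 1e-16)
  expect_true(is.character(got3$p.label))

  expect_error(wilcoxon_signed_rank(1:5, 2:6), "at least 10")
  expect_error(wilcoxon_signed_rank(1:12, 1:11), "length")
})

test_that("cohort filters: age bounds, kinship dedupe, repeated measures", {
  coh <- data.frame(
    id = sprintf("i%02d", 1:8),
    sex = c("f", "f", "f", "m", "m", "f", "m", "f"),
    age = c(39, 40, 70, 71, 55, 55, 55, 55),
    kinship_group = c(NA, NA, NA, NA, "k1", "k1", "k1", NA),
    bmi_1 = c(26.1, 25, 24, 23, 22, 21, 20, 26.1),
    bmi_2 = c(27.4, NA, 23, 24, 21, 22, 19, 27.4),
    stringsAsFactors = FALSE)
  out <- apply_cohort_filters(coh, repeated_measures = list(bmi = c("bmi_1", "bmi_2")))
  expect_false(any(out$age < 40 | out$age > 70))      # 39 and 71 dropped
  expect_true(all(c("i02", "i03") %in% out$id))        # 40 and 70 retained
  expect_equal(out$bmi[out$id == "i08"], 27.4)         # maximal repeat kept
  expect_false(any(c("bmi_1", "bmi_2") %in% names(out)))
  # k1 spans sexes: one male of {i05, i07} kept (lowest id) plus female i06
  expect_true("i05" %in% out$id)
  expect_false("i07" %in% out$id)
  expect_true("i06" %in% out$id)

  # same-sex group of three keeps exactly one representative
  coh3 <- data.frame(id = c("a", "b", "c"), sex = "m", age = 50,
                     kinship_group = "g1", stringsAsFactors = FALSE)
  expect_equal(apply_cohort_filters(coh3)$id, "a")
  expect_error(apply_cohort_filters(data.frame(id = 1)), "required")
})

test_that("repeat_experiment is deterministic and paired across measures", {
  coh <- generate_cohort(simulation_config(3000, sex_ratio = 0, seed = 12))
  ms <- list(crs = c("prs", "bmi", "age"), age = "age")
  r1 <- repeat_experiment(coh, ms, n_repetitions = 2, seed = 99)
  r2 <- repeat_experiment(coh, ms, n_repetitions = 2, seed = 99)
  expect_identical(r1, r2)
  expect_false(identical(
    r1$measures$crs$auc,
    repeat_experiment(coh, ms, n_repetitions = 2, seed = 98)$measures$crs$auc))
  # shared split: test totals are a property of the repetition, not the measure
  expect_equal(r1$test_cases + r1$test_controls, rep(900L, 2))

  expect_error(repeat_experiment(coh, ms, n_repetitions = 1), ">= 2")
  expect_error(repeat_experiment(coh, list(x = "nope"), 2), "unknown measure component")
})

test_that("strong monotone effects give monotone mean OR tendency", {
  cfg <- null_config(20000, seed = 42)
  cfg$beta_bmi <- 1.2
  coh <- generate_cohort(cfg)
  res <- repeat_experiment(coh, list(bmi = c("bmi", "age")),
                           n_repetitions = 10, seed = 7)
  om <- res$measures$bmi$or_mean
  expect_gt(om[100], om[91])
  expect_gt(om[91], om[51])
})
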