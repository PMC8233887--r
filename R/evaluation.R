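#' Per-percentile odds ratios of a score on a test set
#'
#' Individuals are ranked by score (seeded uniform tie-break, as in
#' [fit_quantile_bins()]) and split into `n_bins` equal-size percentile
#' bins 0..`n_bins`-1.  For percentile p with Dp cases and Hp non-cases,
#' and D, H the remaining cases/non-cases,
#' \deqn{OR(p) = (D_p/H_p) / (D_{\neg p}/H_{\neg p}).}
#' A zero cell anywhere in the 2x2 table makes OR(p) undefined (`NA`), with
#' no continuity correction by default; `haldane = TRUE` instead adds 0.5
#' to all four cells (Haldane-Anscombe) so every OR is defined.
#'
#' @param scores numeric score per test individual.
#' @param labels 0/1 disease status; both classes required.
#' @param n_bins number of percentile bins (default 100).
#' @param tiebreak_seed seed of the ranking tie-break.
#' @param haldane logical; apply the +0.5 correction instead of NA.
#' @return data.frame of class `or_profile` with columns `percentile`
#'   (0-based), `D`, `H`, `or`; attributes `total_cases`, `total_controls`.
#' @export
odds_ratio_percentiles <- function(scores, labels, n_bins = 100L,
                                   tiebreak_seed = 1L, haldane = FALSE) {
  labels <- check_binary_labels(labels, require_both_classes = TRUE)
  n <- length(scores)
  if (length(labels) != n) stop("scores and labels differ in length", call. = FALSE)
  if (n < n_bins)
    stop("fewer individuals (", n, ") than percentile bins (", n_bins, ")",
         call. = FALSE)
  tb <- with_seed(tiebreak_seed, runif(n))
  ord <- order(scores, tb)
  bin <- bin_of_rank(n, n_bins)
  n_per <- tabulate(bin, n_bins)
  D <- tabulate(bin[labels[ord] == 1L], n_bins)
  H <- n_per - D
  Dn <- sum(D) - D
  Hn <- sum(H) - H
  or <- if (haldane) {
    ((D + 0.5) / (H + 0.5)) / ((Dn + 0.5) / (Hn + 0.5))
  } else {
    ifelse(D == 0L | H == 0L | Dn == 0L | Hn == 0L,
           NA_real_, (D / H) / (Dn / Hn))
  }
  out <- data.frame(percentile = seq_len(n_bins) - 1L, D = D, H = H, or = or)
  attr(out, "total_cases") <- sum(D)
  attr(out, "total_controls") <- sum(H)
  class(out) <- c("or_profile", "data.frame")
  out
}

# Known component names -> cohort column and bin-model kind.
component_spec <- function(name) {
  switch(name,
    prs = list(column = "raw_prs", kind = "quantile"),
    bmi = list(column = "bmi", kind = "quantile"),
    bw = ,
    birth_weight = list(column = "birth_weight", kind = "quantile"),
    body_size = ,
    body_size_age10 = list(column = "body_size_age10", kind = "categorical"),
    age = list(column = "age", kind = "age_year"),
    stop("unknown measure component: '", name,
         "' (known: prs, bmi, birth_weight, body_size_age10, age)",
         call. = FALSE))
}

fit_component <- function(spec, values, labels, n_bins, tiebreak_seed) {
  switch(spec$kind,
    quantile = fit_quantile_bins(values, labels, n_bins, tiebreak_seed),
    categorical = fit_categorical_bins(values, labels),
    age_year = fit_age_bins(values, labels))
}

#' Evaluate measures over repeated random train/test splits
#'
#' The resampling protocol of the composite-score analysis: per repetition
#' one shared random split (default 70 percent training), every measure
#' fitted on the identical training set (component bin models, then simplex
#' weights maximizing training AUC) and evaluated on the identical test set
#' (test AUC and per-percentile odds ratios), so that measures are paired
#' across repetitions.  Per-percentile OR means and SDs are taken over
#' repetitions, excluding undefined ORs.
#'
#' @param cohort cohort data.frame (already sex-stratified and filtered;
#'   see [apply_cohort_filters()]).
#' @param measures named list; each element is a character vector of
#'   component names among `prs`, `bmi`, `birth_weight`, `body_size_age10`,
#'   `age` (a single `"age"` component is the age-alone measure, which has
#'   no weights to learn).
#' @param n_repetitions number of random splits (>= 2, default 1000).
#' @param train_fraction fraction of individuals in the training set.
#' @param n_bins percentile bins for both risk transforms and OR profiles.
#' @param step weight-grid step (default 0.025).
#' @param seed master seed; each repetition derives its own sub-seed, so
#'   results do not depend on execution order.
#' @param haldane passed to [odds_ratio_percentiles()].
#' @return An object of class `repeat_result`: per measure a list with
#'   `or_mean`, `or_sd`, `n_defined` (per percentile), `or_matrix`
#'   (repetitions x percentiles), `auc` (test AUC per repetition),
#'   `training_auc`, `corner_auc` (repetitions x components) and `weights`
#'   (repetitions x components); plus `n_repetitions`, `measures`, `seed`,
#'   and per-repetition test case/control totals.
#' @export
repeat_experiment <- function(cohort, measures, n_repetitions = 1000L,
                              train_fraction = 0.7, n_bins = 100L,
                              step = 0.025, seed = 1L, haldane = FALSE) {
  if (n_repetitions < 2L)
    stop("n_repetitions must be >= 2 (SDs are taken over repetitions)",
         call. = FALSE)
  if (is.null(names(measures)) || any(!nzchar(names(measures))))
    stop("measures must be a named list", call. = FALSE)
  # resolve all components up front: unknown names fail before computation
  specs <- lapply(measures, function(comps) lapply(comps, component_spec))
  comp_names <- unique(unlist(measures, use.names = FALSE))
  comp_specs <- lapply(comp_names, component_spec)
  names(comp_specs) <- comp_names
  missing_cols <- setdiff(vapply(comp_specs, `[[`, "", "column"), names(cohort))
  if (length(missing_cols))
    stop("cohort lacks required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  y <- check_binary_labels(cohort$t2d, require_both_classes = TRUE)
  n <- nrow(cohort)
  n_train <- floor(n * train_fraction)
  if (n_train < n_bins || n - n_train < n_bins)
    stop("train or test set smaller than n_bins; enlarge the cohort",
         call. = FALSE)

  rep_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_repetitions))
  k_of <- vapply(measures, length, 0L)
  res <- lapply(names(measures), function(m) {
    k <- k_of[[m]]
    list(or_matrix = matrix(NA_real_, n_repetitions, n_bins),
         auc = numeric(n_repetitions),
         training_auc = numeric(n_repetitions),
         corner_auc = matrix(NA_real_, n_repetitions, k,
                             dimnames = list(NULL, measures[[m]])),
         weights = matrix(NA_real_, n_repetitions, k,
                          dimnames = list(NULL, measures[[m]])))
  })
  names(res) <- names(measures)
  test_cases <- integer(n_repetitions)
  test_controls <- integer(n_repetitions)

  for (r in seq_len(n_repetitions)) {
    rs <- rep_seeds[r]
    idx_tr <- with_seed(rs, sample.int(n, n_train))
    in_tr <- logical(n); in_tr[idx_tr] <- TRUE
    y_tr <- y[in_tr]; y_te <- y[!in_tr]
    test_cases[r] <- sum(y_te)
    test_controls[r] <- length(y_te) - test_cases[r]

    # one bin model per distinct component, shared by all measures
    risks_tr <- risks_te <- list()
    for (cn in comp_names) {
      sp <- comp_specs[[cn]]
      v <- cohort[[sp$column]]
      mod <- fit_component(sp, v[in_tr], y_tr, n_bins, rs)
      risks_tr[[cn]] <- assign_risk(mod, v[in_tr])
      risks_te[[cn]] <- assign_risk(mod, v[!in_tr])
    }

    for (m in names(measures)) {
      comps <- measures[[m]]
      rt <- do.call(cbind, risks_tr[comps])
      re <- do.call(cbind, risks_te[comps])
      if (length(comps) == 1L) {
        w <- 1
        res[[m]]$training_auc[r] <- roc_auc(rt[, 1L], y_tr)
        res[[m]]$corner_auc[r, 1L] <- res[[m]]$training_auc[r]
      } else {
        fs <- fit_weights(rt, y_tr, step)
        w <- fs$weights
        res[[m]]$training_auc[r] <- fs$training_auc
        res[[m]]$corner_auc[r, ] <- fs$corner_auc
      }
      res[[m]]$weights[r, ] <- w
      s_te <- compose_score(w, re)
      res[[m]]$auc[r] <- roc_auc(s_te, y_te)
      orp <- odds_ratio_percentiles(s_te, y_te, n_bins, tiebreak_seed = rs,
                                    haldane = haldane)
      res[[m]]$or_matrix[r, ] <- orp$or
    }
  }

  for (m in names(measures)) {
    om <- res[[m]]$or_matrix
    res[[m]]$or_mean <- colMeans(om, na.rm = TRUE)
    res[[m]]$or_sd <- apply(om, 2L, stats::sd, na.rm = TRUE)
    res[[m]]$n_defined <- colSums(!is.na(om))
  }
  structure(list(measures = res,
                 measure_components = measures,
                 n_repetitions = as.integer(n_repetitions),
                 train_fraction = train_fraction,
                 n_bins = as.integer(n_bins), step = step,
                 seed = as.integer(seed),
                 test_cases = test_cases, test_controls = test_controls),
            class = "repeat_result")
}

#' @export
print.repeat_result <- function(x, ...) {
  cat(sprintf("<repeat_result: %d repetitions, %d measures (%s), %d bins>\n",
              x$n_repetitions, length(x$measures),
              paste(names(x$measures), collapse = ", "), x$n_bins))
  for (m in names(x$measures)) {
    cat(sprintf("  %-14s mean test AUC %.4f, top-percentile mean OR %.3f\n",
                m, mean(x$measures[[m]]$auc),
                x$measures[[m]]$or_mean[x$n_bins]))
  }
  invisible(x)
}

#' Compare two measures from a repeat_result
#'
#' Paired comparisons across repetitions (valid because every repetition
#' uses one shared split): a Wilcoxon signed-rank test on the test AUC
#' distributions and, per percentile, on the OR distributions (pairs with
#' an undefined OR in either measure are dropped; fewer than 10 remaining
#' pairs yields NA for that percentile).
#'
#' @param result a [repeat_experiment()] result.
#' @param a,b measure names present in `result`.
#' @return list with `measures`, `auc_test` (the signed-rank result on
#'   AUCs) and `or_pvalue` (numeric per percentile).
#' @export
compare_measures <- function(result, a, b) {
  stopifnot(inherits(result, "repeat_result"),
            a %in% names(result$measures), b %in% names(result$measures))
  ra <- result$measures[[a]]; rb <- result$measures[[b]]
  auc_test <- wilcoxon_signed_rank(ra$auc, rb$auc)
  orp <- vapply(seq_len(result$n_bins), function(p) {
    x <- ra$or_matrix[, p]; yv <- rb$or_matrix[, p]
    ok <- !is.na(x) & !is.na(yv)
    if (sum(ok) < 10L) return(NA_real_)
    wilcoxon_signed_rank(x[ok], yv[ok])$p.value
  }, numeric(1))
  list(measures = c(a, b), auc_test = auc_test, or_pvalue = orp)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired test with zero-difference exclusion.  After dropping
#' zero differences, the exact null distribution of the positive-rank sum
#' W+ is computed for n <= 25 by dynamic programming over (doubled)
#' midranks -- equivalent to enumerating all 2^n sign assignments and valid
#' under ties; above 25 a tie-corrected normal approximation (no continuity
#' correction) is used.  P-values below 1e-300 are additionally reported as
#' the underflow-safe label `"< 1e-300"`.
#'
#' @param paired_a,paired_b equal-length numeric vectors (length >= 10).
#' @return list with `statistic` (W+), `p.value`, `p.label`, `n_used`
#'   (nonzero differences) and `method`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b))
    stop("paired vectors differ in length", call. = FALSE)
  if (length(paired_a) < 10L)
    stop("need at least 10 pairs", call. = FALSE)
  d <- paired_a - paired_b
  if (anyNA(d)) stop("missing values in differences", call. = FALSE)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero; p = 1")
    return(list(statistic = 0, p.value = 1, p.label = "1", n_used = 0L,
                method = "degenerate"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25L) {
    # exact: counts of 2*W+ over all 2^n sign assignments, tie-aware
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    cnt <- numeric(tot + 1L)
    cnt[1L] <- 1
    for (v in r2)
      cnt[(v + 1L):(tot + 1L)] <- cnt[(v + 1L):(tot + 1L)] + cnt[1L:(tot + 1L - v)]
    w2 <- as.integer(round(2 * W))
    p_le <- sum(cnt[1L:(w2 + 1L)]) / 2^n
    p_ge <- sum(cnt[(w2 + 1L):(tot + 1L)]) / 2^n
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_t <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_t^3 - tie_t) / 48
    z <- (W - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation, tie-corrected"
  }
  label <- if (p < 1e-300) "< 1e-300" else format(p)
  list(statistic = W, p.value = p, p.label = label, n_used = n,
       method = method)
}

#' Apply the cohort inclusion filters
#'
#' Drops rows outside the (inclusive) age range, optionally collapses
#' repeated measurements of a phenotype to their maximum, and keeps a
#' single representative (the lowest id) of each same-sex kinship group.
#'
#' @param cohort cohort data.frame with at least `id`, `sex`, `age`.
#' @param age_range inclusive integer bounds (default 40--70).
#' @param dedupe_kinship keep one representative per (sex, kinship_group)
#'   when a `kinship_group` column is present; rows with NA group are kept.
#' @param repeated_measures optional named list mapping a target column to
#'   the source columns holding its repeated measurements; the row maximum
#'   (NA-removed) is stored in the target and the sources are dropped.
#' @return the filtered cohort data.frame.
#' @export
apply_cohort_filters <- function(cohort, age_range = c(40L, 70L),
                                 dedupe_kinship = TRUE,
                                 repeated_measures = NULL) {
  req <- c("id", "sex", "age")
  miss <- setdiff(req, names(cohort))
  if (length(miss))
    stop("cohort lacks required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.null(repeated_measures)) {
    for (target in names(repeated_measures)) {
      src <- repeated_measures[[target]]
      miss <- setdiff(src, names(cohort))
      if (length(miss))
        stop("repeated-measure columns not found: ",
             paste(miss, collapse = ", "), call. = FALSE)
      cohort[[target]] <- do.call(pmax, c(unname(cohort[src]), list(na.rm = TRUE)))
      cohort <- cohort[, setdiff(names(cohort), setdiff(src, target)),
                       drop = FALSE]
    }
  }
  cohort <- cohort[cohort$age >= age_range[1] & cohort$age <= age_range[2], ,
                   drop = FALSE]
  if (dedupe_kinship && "kinship_group" %in% names(cohort)) {
    grouped <- !is.na(cohort$kinship_group)
    if (any(grouped)) {
      g <- cohort[grouped, c("id", "sex", "kinship_group")]
      g <- g[order(g$sex, g$kinship_group, g$id), , drop = FALSE]
      drop_ids <- g$id[duplicated(g[, c("sex", "kinship_group")])]
      cohort <- cohort[!cohort$id %in% drop_ids, , drop = FALSE]
    }
  }
  rownames(cohort) <- NULL
  cohort
}
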