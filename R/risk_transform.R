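#' Prevalence-scale risk transforms (bin models)
#'
#' A *bin model* maps a measure to the empirical disease prevalence among
#' training individuals with similar values of that measure.  Three kinds
#' exist:
#' \describe{
#'   \item{`quantile`}{individuals are sorted by value and split into
#'     `n_bins` (default 100) equal-size rank blocks; each bin's risk is
#'     its case fraction (e.g. a bin in which 5 percent of members are
#'     cases has risk 0.05).  Ties are broken by a seeded uniform draw so
#'     the blocks are exactly equal-size even on heavily tied measures;
#'     the tiebreak seed is recorded in the model.}
#'   \item{`categorical`}{one bin per observed label.}
#'   \item{`age_year`}{one bin per observed (rounded) year of age.}
#' }
#' Fitted models are applied to new data with [assign_risk()]: quantile
#' models use the training-derived lower bin edges as half-open intervals
#' (out-of-range values are clamped to the extreme bins), categorical
#' models use exact label lookup (unseen labels are an error), and age
#' models map unseen years to the nearest observed year (ties to the
#' younger year).  Bins with zero cases get prevalence 0 -- no smoothing.
#'
#' @param values numeric measure (quantile), labels (categorical) or
#'   integer ages (age_year), one per individual.
#' @param labels 0/1 disease status per individual.
#' @param n_bins number of quantile bins (default 100 percentile bins).
#' @param tiebreak_seed integer seed of the uniform tie-break draw.
#' @return An object of class `bin_model`: a list with `kind`, `edges`
#'   (lower edges / label set / year set), `prevalence` and `n_per_bin`
#'   per bin, `n_bins`, `overall` (training prevalence) and, for quantile
#'   models, `tiebreak_seed`.
#' @examples
#' m <- fit_quantile_bins(1:200, rep(c(0, 1), 100), n_bins = 100)
#' table(m$n_per_bin)   # every bin has exactly 2 members
#' @name bin_model
NULL

#' @rdname bin_model
#' @export
fit_quantile_bins <- function(values, labels, n_bins = 100L, tiebreak_seed = 1L) {
  labels <- check_binary_labels(labels)
  if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
  n <- length(values)
  if (length(labels) != n) stop("values and labels differ in length", call. = FALSE)
  if (n < n_bins)
    stop("fewer individuals (", n, ") than bins (", n_bins, ")", call. = FALSE)
  tb <- with_seed(tiebreak_seed, runif(n))
  ord <- order(values, tb)
  bin <- bin_of_rank(n, n_bins)
  sorted <- values[ord]
  n_per <- tabulate(bin, n_bins)
  cases <- tabulate(bin[labels[ord] == 1L], n_bins)
  structure(list(
    kind = "quantile",
    edges = sorted[match(seq_len(n_bins), bin)],
    prevalence = cases / n_per,
    n_per_bin = n_per,
    n_bins = as.integer(n_bins),
    overall = sum(labels) / n,
    tiebreak_seed = as.integer(tiebreak_seed)),
    class = "bin_model")
}

#' @rdname bin_model
#' @export
fit_categorical_bins <- function(values, labels) {
  labels <- check_binary_labels(labels)
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
  lv <- sort(unique(as.character(values)))
  idx <- match(as.character(values), lv)
  n_per <- tabulate(idx, length(lv))
  cases <- tabulate(idx[labels == 1L], length(lv))
  structure(list(
    kind = "categorical",
    edges = lv,
    prevalence = cases / n_per,
    n_per_bin = n_per,
    n_bins = length(lv),
    overall = sum(labels) / length(labels)),
    class = "bin_model")
}

#' @rdname bin_model
#' @export
fit_age_bins <- function(ages, labels) {
  labels <- check_binary_labels(labels)
  if (length(ages) == 0L) stop("empty input", call. = FALSE)
  if (anyNA(ages) || any(ages != round(ages)))
    stop("ages must be integer years with no NA", call. = FALSE)
  yrs <- sort(unique(as.integer(ages)))
  idx <- match(as.integer(ages), yrs)
  n_per <- tabulate(idx, length(yrs))
  cases <- tabulate(idx[labels == 1L], length(yrs))
  structure(list(
    kind = "age_year",
    edges = yrs,
    prevalence = cases / n_per,
    n_per_bin = n_per,
    n_bins = length(yrs),
    overall = sum(labels) / length(labels)),
    class = "bin_model")
}

#' Assign fitted bin risks to (new) values
#'
#' @param model a fitted [bin_model].
#' @param values values on the same scale the model was fitted on.
#' @return numeric risk (bin prevalence) per individual.
#' @export
assign_risk <- function(model, values) {
  stopifnot(inherits(model, "bin_model"))
  if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
  switch(model$kind,
    quantile = {
      # lower edges; intervals [e_k, e_{k+1}), below-range clamps to bin 1,
      # the last interval is unbounded above
      bin <- findInterval(values, model$edges[-1L]) + 1L
      model$prevalence[bin]
    },
    categorical = {
      idx <- match(as.character(values), model$edges)
      if (anyNA(idx))
        stop("labels never seen at fit: ",
             paste(unique(values[is.na(idx)]), collapse = ", "), call. = FALSE)
      model$prevalence[idx]
    },
    age_year = {
      yrs <- model$edges
      i <- findInterval(values, yrs)
      i[i == 0L] <- 1L
      j <- pmin(i + 1L, length(yrs))
      # nearest observed year; ties go to the younger year
      pick <- ifelse(values - yrs[i] <= yrs[j] - values, i, j)
      model$prevalence[pick]
    },
    stop("unknown bin model kind: ", model$kind, call. = FALSE))
}

#' @export
print.bin_model <- function(x, ...) {
  cat(sprintf("<bin_model: %s, %d bins, training prevalence %.4f>\n",
              x$kind, x$n_bins, x$overall))
  invisible(x)
}
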