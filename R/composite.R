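#' Enumerate simplex weight vectors on a step lattice
#'
#' All nonnegative weight combinations summing to 1 on the lattice with the
#' given step, in deterministic lexicographic order (first component major,
#' descending; then second component descending).  With step 0.025 this
#' yields 41 vectors for 2 components and 861 for 3.
#'
#' @param n_components 1, 2 or 3 risk components.
#' @param step lattice step; `1/step` must be an integer.
#' @return numeric matrix, one weight vector per row.
#' @examples
#' nrow(enumerate_weights(3, 0.025))  # 861
#' enumerate_weights(3, 0.5)          # the 6 lattice points of i+j+k = 2
#' @export
enumerate_weights <- function(n_components, step = 0.025) {
  if (!n_components %in% 1:3)
    stop("n_components must be 1, 2 or 3", call. = FALSE)
  L <- round(1 / step)
  if (abs(L - 1 / step) > 1e-9)
    stop("1/step must be an integer (got step = ", step, ")", call. = FALSE)
  if (n_components == 1L) return(matrix(1, 1L, 1L))
  if (n_components == 2L) {
    a <- L:0
    return(cbind(a, L - a, deparse.level = 0) / L)
  }
  a <- rep.int(L:0, 1L:(L + 1L))
  b <- unlist(lapply(L:0, function(i) (L - i):0), use.names = FALSE)
  cbind(a, b, L - a - b, deparse.level = 0) / L
}

#' Compose a weighted risk score
#'
#' The composite score of individual i is the weighted sum of its component
#' risks, e.g. \eqn{CRS_i = \alpha GR_i + \beta PR_i + \gamma AR_i} with
#' \eqn{\alpha+\beta+\gamma = 1}, all nonnegative.  Being a convex
#' combination of prevalences, the result lies in \[0, 1\].
#'
#' @param weights numeric weight vector, one entry per component.
#' @param risks numeric matrix of component risks, individuals x components
#'   (a vector is accepted for a single component).
#' @return numeric score per individual.
#' @export
compose_score <- function(weights, risks) {
  if (is.vector(risks)) risks <- matrix(risks, ncol = 1L)
  if (length(weights) != ncol(risks))
    stop("component count mismatch: ", length(weights), " weights vs ",
         ncol(risks), " risk columns", call. = FALSE)
  drop(as.matrix(risks) %*% as.numeric(weights))
}

#' Rank-statistic ROC AUC
#'
#' The probability that a randomly chosen case outscores a randomly chosen
#' control, ties counted one half (the Mann-Whitney statistic); identical to
#' the trapezoidal area under the ROC curve.
#'
#' @param scores numeric score per individual.
#' @param labels 0/1 disease status; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_binary_labels(labels, require_both_classes = TRUE)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  n1 <- sum(labels)
  n0 <- length(labels) - n1
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percentile-binned ROC AUC variant
#'
#' AUC computed after collapsing scores to their percentile-bin index
#' (provided for reproducing percentile-level ROC displays; weight fitting
#' uses the continuous [roc_auc()]).
#'
#' @inheritParams roc_auc
#' @param n_bins number of rank bins.
#' @param tiebreak_seed seed of the uniform tie-break used in ranking.
#' @return AUC in \[0, 1\].
#' @export
roc_auc_binned <- function(scores, labels, n_bins = 100L, tiebreak_seed = 1L) {
  labels <- check_binary_labels(labels, require_both_classes = TRUE)
  n <- length(scores)
  tb <- with_seed(tiebreak_seed, runif(n))
  ord <- order(scores, tb)
  bin <- integer(n)
  bin[ord] <- bin_of_rank(n, n_bins)
  roc_auc(bin, labels)
}

#' Fit simplex weights by exhaustive grid search on training AUC
#'
#' Evaluates every weight vector of [enumerate_weights()] on the training
#' component risks and returns the one maximizing the continuous rank AUC;
#' ties are broken by the earliest vector in enumeration order.  Because the
#' corner vectors are on the grid, the fitted training AUC is always at
#' least the AUC of every single component.
#'
#' @param risks numeric matrix of training component risks (individuals x
#'   components, 1 to 3 columns).
#' @param labels 0/1 training disease status; both classes required.
#' @param step grid step (default 0.025).
#' @return An object of class `fitted_score`: list with `weights` (named by
#'   risk column names when present), `training_auc`, `corner_auc` (AUC of
#'   each component alone), `grid_step` and `n_grid`.
#' @export
fit_weights <- function(risks, labels, step = 0.025) {
  if (is.vector(risks)) risks <- matrix(risks, ncol = 1L)
  risks <- as.matrix(risks)
  labels <- check_binary_labels(labels, require_both_classes = TRUE)
  if (nrow(risks) != length(labels))
    stop("risks and labels differ in length", call. = FALSE)
  grid <- enumerate_weights(ncol(risks), step)
  cl <- collapse_risks(risks, labels)
  aucs <- cpp_grid_auc(cl$risks, cl$n_case, cl$n_ctrl, grid)
  best <- which.max(aucs)  # first maximum = earliest in enumeration order
  corner <- vapply(seq_len(ncol(risks)), function(j) {
    aucs[which(grid[, j] == 1)[1L]]
  }, numeric(1))
  w <- grid[best, ]
  names(w) <- colnames(risks)
  names(corner) <- colnames(risks)
  structure(list(weights = w,
                 training_auc = aucs[best],
                 corner_auc = corner,
                 grid_step = step,
                 n_grid = nrow(grid)),
            class = "fitted_score")
}

#' @export
print.fitted_score <- function(x, ...) {
  cat(sprintf("<fitted_score: weights (%s), training AUC %.4f, grid %d @ step %g>\n",
              paste(sprintf("%.3f", x$weights), collapse = ", "),
              x$training_auc, x$n_grid, x$grid_step))
  invisible(x)
}

# Collapse duplicate component-risk rows into unique rows with case/control
# counts; the grid AUC then sorts u unique rows instead of n individuals and
# handles ties between identical rows exactly.
collapse_risks <- function(risks, labels) {
  key <- do.call(paste, c(as.data.frame(risks), list(sep = "\r")))
  first <- !duplicated(key)
  f <- factor(key, levels = key[first])
  cnt <- rowsum(cbind(labels, 1L - labels), f, reorder = FALSE)
  list(risks = risks[first, , drop = FALSE],
       n_case = as.numeric(cnt[, 1L]),
       n_ctrl = as.numeric(cnt[, 2L]))
}
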