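#' Compute the raw polygenic risk score from dosages and marker weights
#'
#' The raw PRS of an individual is the weighted sum of allele dosages over
#' the scored markers, \eqn{\sum_i w_i G_i} with \eqn{G_i \in \{0,1,2\}}.
#' Columns are scored in the order of the weight table (fixed summation
#' order for float reproducibility).  Missing dosages are imputed with the
#' column mean observed dosage, the standard mean-dosage convention, and a
#' per-individual missingness count is returned alongside the score.
#'
#' No allele flipping or strand reconciliation is attempted: the weight
#' table is assumed to be on the same effect-allele orientation as the
#' dosage matrix.  When `dosage_alleles` is supplied (a named character
#' vector, marker id -> counted allele), labels are checked against the
#' weight table's `effect_allele` and any mismatch is an error.
#'
#' @param dosages numeric matrix, rows = individuals (rownames used as ids),
#'   columns = markers (colnames must be marker ids); entries 0/1/2 or NA.
#' @param weights data.frame with columns `marker_id`, `effect_allele`,
#'   `weight`; marker ids unique, weights finite.
#' @param dosage_alleles optional named character vector giving the counted
#'   allele of each dosage column, for the mismatch check.
#' @return data.frame with columns `id`, `raw_prs`, `n_missing`.
#' @examples
#' d <- matrix(c(2, 1, 0), nrow = 1,
#'             dimnames = list("s1", c("m1", "m2", "m3")))
#' w <- data.frame(marker_id = c("m1", "m2", "m3"),
#'                 effect_allele = c("A", "C", "G"),
#'                 weight = c(0.5, -0.2, 0.3))
#' compute_raw_prs(d, w)$raw_prs  # 0.8
#' @export
compute_raw_prs <- function(dosages, weights, dosage_alleles = NULL) {
  if (!is.matrix(dosages) && !is.data.frame(dosages))
    stop("dosages must be a matrix or data.frame", call. = FALSE)
  dosages <- as.matrix(dosages)
  req <- c("marker_id", "effect_allele", "weight")
  if (!all(req %in% names(weights)))
    stop("weights must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  if (anyDuplicated(weights$marker_id))
    stop("duplicated marker_id in weight table", call. = FALSE)
  if (!all(is.finite(weights$weight)))
    stop("weights must be finite", call. = FALSE)
  if (is.null(colnames(dosages)))
    stop("dosage matrix must have marker ids as column names", call. = FALSE)

  unknown <- setdiff(colnames(dosages), weights$marker_id)
  if (length(unknown))
    stop("markers in dosage matrix absent from weight table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  wt <- weights[weights$marker_id %in% colnames(dosages), , drop = FALSE]
  if (nrow(wt) == 0L)
    stop("zero overlapping markers between dosages and weights", call. = FALSE)
  if (!is.null(dosage_alleles)) {
    da <- dosage_alleles[wt$marker_id]
    bad <- which(!is.na(da) & da != wt$effect_allele)
    if (length(bad))
      stop("effect-allele mismatch for markers: ",
           paste(wt$marker_id[bad], collapse = ", "), call. = FALSE)
  }

  # weight-table column order fixes the summation order
  x <- dosages[, wt$marker_id, drop = FALSE]
  ok <- is.na(x) | x %in% c(0, 1, 2)
  if (!all(ok))
    stop("dosage entries must be 0, 1, 2 or NA", call. = FALSE)
  n_missing <- as.integer(rowSums(is.na(x)))
  if (any(n_missing > 0L)) {
    cm <- colMeans(x, na.rm = TRUE)
    cm[is.nan(cm)] <- 0  # marker entirely missing: contributes 0
    idx <- which(is.na(x))
    x[idx] <- cm[((idx - 1L) %/% nrow(x)) + 1L]
  }
  ids <- rownames(dosages)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(dosages)))
  data.frame(id = ids,
             raw_prs = drop(x %*% wt$weight),
             n_missing = n_missing,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a marker weight table (three-column scoring-file layout)
#'
#' Tab-delimited with header columns `marker_id`, `effect_allele`, `weight`.
#' @param path file path.
#' @return data.frame suitable for [compute_raw_prs()].
#' @export
read_weight_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("marker_id", "effect_allele", "weight")
  if (!all(req %in% names(df)))
    stop("weight table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  df$marker_id <- as.character(df$marker_id)
  df
}

#' Read a dosage matrix (first column id, remaining columns marker ids)
#'
#' Tab-delimited; missing dosages encoded `NA`.
#' @param path file path.
#' @return numeric matrix with individual ids as rownames.
#' @export
read_dosage_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}
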