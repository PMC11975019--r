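#' k-NN condition enrichment in an embedding
#'
#' For every cell, the fraction of each condition among its \code{k}
#' nearest neighbours (Euclidean distance, self excluded) is compared with
#' the expected fraction under random assignment, which is simply the
#' global fraction of that condition among the analysed cells:
#' enrichment = observed fraction - expected fraction. Rows therefore sum
#' to zero. Distance ties are broken by cell index so results are exactly
#' reproducible.
#'
#' @param coords Cells x d coordinate matrix (d >= 2).
#' @param labels Per-cell condition labels (character or factor), parallel
#'   to the rows of \code{coords}.
#' @param k Neighbourhood size (default 100); must be < number of cells.
#' @return Cells x conditions matrix of enrichments in [-1, 1].
#' @export
knn_condition_enrichment <- function(coords, labels, k = 100L) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords)) || ncol(coords) < 2L)
    stop("coords must be a finite matrix with at least 2 columns")
  n <- nrow(coords)
  if (k >= n) stop("k must be smaller than the number of cells")
  labels <- as.character(labels)
  stopifnot(length(labels) == n)
  conds <- sort(unique(labels))
  expected <- vapply(conds, function(cc) mean(labels == cc), numeric(1))
  nn <- knn_indices(coords, k)
  lab_idx <- match(labels, conds)
  obs <- matrix(0, n, length(conds), dimnames = list(rownames(coords), conds))
  neigh <- matrix(lab_idx[nn], n, k)
  for (ci in seq_along(conds))
    obs[, ci] <- rowSums(neigh == ci) / k
  sweep(obs, 2L, expected)
}

#' k-NN smoothing of per-cell values
#'
#' Each cell's value is replaced by the mean over the cell itself and its
#' \code{k} nearest neighbours in the embedding (set
#' \code{include_self = FALSE} to average neighbours only). Smoothing is a
#' contraction: the output range is contained in the input range.
#'
#' @param values Numeric vector, one value per cell.
#' @param coords Cells x d coordinate matrix.
#' @param k Number of neighbours (default 20).
#' @param include_self Include the cell's own value in the mean.
#' @return Numeric vector of smoothed values.
#' @export
knn_smooth <- function(values, coords, k = 20L, include_self = TRUE) {
  coords <- as.matrix(coords)
  stopifnot(length(values) == nrow(coords))
  nn <- knn_indices(coords, k)
  smoothed <- rowMeans(matrix(values[nn], nrow(coords), k))
  if (include_self) (values + k * smoothed) / (k + 1) else smoothed
}
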