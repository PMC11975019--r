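#' QC-filter and depth-normalize a spatial section
#'
#' Bins with fewer than \code{min_reads} total reads are dropped; the
#' remaining bins' counts are scaled so every bin's total equals the mean
#' depth of the retained bins, and a log2(x + 1) transform of the
#' normalized counts is stored for embedding.
#'
#' @param coords Bins x 2 coordinate data.frame/matrix (columns x, y).
#' @param counts Bins x genes count matrix (dense or sparse), rows
#'   matching \code{coords}.
#' @param min_reads Minimum reads per retained bin (inclusive; default
#'   300).
#' @return A list of class \code{"spatial_section"}: \code{coords},
#'   \code{counts} (raw, retained bins), \code{norm}, \code{logcounts},
#'   \code{depth}.
#' @export
spatial_qc_normalize <- function(coords, counts, min_reads = 300L) {
  counts <- as_csparse(counts)
  stopifnot(nrow(coords) == nrow(counts))
  depth <- Matrix::rowSums(counts)
  keep <- threshold_at_least(depth, min_reads)
  if (!any(keep)) stop("no bins pass the read-depth filter")
  counts <- counts[keep, , drop = FALSE]
  coords <- as.data.frame(coords)[keep, , drop = FALSE]
  depth <- depth[keep]
  target <- mean(depth)
  norm <- as.matrix(counts) * (target / depth)
  structure(list(coords = coords, counts = counts, norm = norm,
                 logcounts = log2(norm + 1), depth = depth),
            class = "spatial_section")
}

#' @export
print.spatial_section <- function(x, ...) {
  cat("Spatial section:", nrow(x$coords), "bins,", ncol(x$counts),
      "genes; mean depth", round(mean(x$depth)), "\n")
  invisible(x)
}

#' Call adenoma bins from smoothed marker expression
#'
#' PCA (top \code{n_pcs} components of the log-normalized counts) defines
#' an expression embedding; the marker gene's normalized expression is
#' smoothed over each bin's \code{k} nearest neighbours in that embedding,
#' z-scored across bins, and bins with smoothed z at or above
#' \code{z_min} (inclusive) are called.
#'
#' @param section A [spatial_qc_normalize()] result.
#' @param marker Marker gene name (e.g. Axin2).
#' @param k Smoothing neighbourhood size (default 20).
#' @param z_min Calling threshold on the smoothed z-score (inclusive,
#'   default 1).
#' @param n_pcs Number of principal components (default 20).
#' @return Integer indices of called bins (into the section's rows), with
#'   attributes \code{z} (smoothed z per bin) and \code{degenerate}
#'   (TRUE when the smoothed marker is constant, in which case no bins
#'   are called).
#' @export
call_adenoma_bins <- function(section, marker, k = 20L, z_min = 1,
                              n_pcs = 20L) {
  stopifnot(inherits(section, "spatial_section"),
            marker %in% colnames(section$norm))
  n_pcs <- min(n_pcs, nrow(section$logcounts) - 1L,
               ncol(section$logcounts))
  pcs <- stats::prcomp(section$logcounts, rank. = n_pcs,
                       center = TRUE, scale. = FALSE)$x
  sm <- knn_smooth(section$norm[, marker], pcs, k = k)
  sdv <- stats::sd(sm)
  if (sdv == 0) {
    out <- integer(0)
    attr(out, "z") <- rep(NA_real_, length(sm))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  z <- (sm - mean(sm)) / sdv
  out <- which(threshold_at_least(z, z_min))
  attr(out, "z") <- z
  attr(out, "degenerate") <- FALSE
  out
}

#' Segment adenoma bins into tumors by spatial graph communities
#'
#' A k = 5 nearest-neighbour graph over the spatial coordinates of the
#' called adenoma bins is clustered with the Louvain modularity algorithm;
#' each community is one tumor. With fewer than k + 1 bins a single tumor
#' is returned, flagged.
#'
#' @param section A [spatial_qc_normalize()] result.
#' @param adenoma_bins Indices from [call_adenoma_bins()].
#' @param k Spatial neighbourhood size (default 5).
#' @param resolution Louvain resolution. The default 0.1 keeps contiguous
#'   regions up to roughly a hundred bins as single communities; larger
#'   values fragment large tumors (see the methods vignette).
#' @param seed Integer seed (Louvain tie-breaking).
#' @return A list of class \code{"tumor_calls"}: \code{tumor} (named
#'   integer vector, bin name to tumor id, ids ordered by decreasing
#'   size), \code{bins} (indices), \code{flagged} (TRUE when too few bins
#'   for the graph).
#' @export
segment_tumors <- function(section, adenoma_bins, k = 5L, resolution = 0.1,
                           seed = 1L) {
  stopifnot(inherits(section, "spatial_section"))
  xy <- as.matrix(section$coords[adenoma_bins, c("x", "y")])
  n <- nrow(xy)
  if (n == 0L) stop("no adenoma bins to segment")
  if (n < k + 1L) {
    tumor <- stats::setNames(rep(1L, n), rownames(xy))
    return(structure(list(tumor = tumor, bins = adenoma_bins,
                          flagged = TRUE), class = "tumor_calls"))
  }
  nn <- knn_indices(xy, k)
  el <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  g <- igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
  memb <- with_seed(seed,
    igraph::membership(igraph::cluster_louvain(g, resolution = resolution)))
  # relabel communities by decreasing size (ties: first occurrence)
  sizes <- table(memb)
  new_id <- stats::setNames(seq_along(sizes),
                            names(sizes)[order(-as.integer(sizes),
                                               as.integer(names(sizes)))])
  tumor <- stats::setNames(as.integer(new_id[as.character(memb)]),
                           rownames(xy))
  structure(list(tumor = tumor, bins = adenoma_bins, flagged = FALSE),
            class = "tumor_calls")
}

#' @export
print.tumor_calls <- function(x, ...) {
  cat("Tumor calls:", max(x$tumor), "tumors over", length(x$tumor),
      "adenoma bins\n")
  print(table(x$tumor))
  invisible(x)
}

#' Score tumors for a gene program
#'
#' Raw counts are pseudobulked by tumor and each tumor pseudobulk is
#' scored on the program gene set with the background-corrected deviation
#' statistic ([deviation_scores()], 20 expression bins), treating tumors
#' as cells. Tumors with score strictly greater than
#' \code{high_threshold} (default 1.5) are flagged high.
#'
#' @param section A [spatial_qc_normalize()] result.
#' @param tumors A [segment_tumors()] result.
#' @param program_genes Character vector of program genes (intersected
#'   with the genes present), or a \code{list(members, weights)} set.
#' @param n_background,n_bins Background specification for
#'   [deviation_scores()].
#' @param high_threshold High-tumor threshold (exclusive).
#' @param seed Integer seed for background sampling.
#' @return Data.frame \code{tumor}, \code{n_bins}, \code{score},
#'   \code{is_high}.
#' @export
score_tumors <- function(section, tumors, program_genes,
                         n_background = 250L, n_bins = 20L,
                         high_threshold = 1.5, seed = 1L) {
  stopifnot(inherits(section, "spatial_section"),
            inherits(tumors, "tumor_calls"))
  if (!is.list(program_genes))
    program_genes <- list(members = intersect(program_genes,
                                              colnames(section$counts)))
  if (!length(program_genes$members)) stop("no program genes present")
  grp <- stats::setNames(sprintf("tumor_%02d", tumors$tumor),
                         names(tumors$tumor))
  pb <- pseudobulk(section$counts[names(grp), , drop = FALSE], grp)
  sc <- deviation_scores(pb$counts, list(program = program_genes),
                         n_background = n_background, n_bins = n_bins,
                         seed = seed)
  ids <- sort(unique(tumors$tumor))
  score <- sc[sprintf("tumor_%02d", ids), "program"]
  data.frame(tumor = ids,
             n_bins = as.integer(table(tumors$tumor)[as.character(ids)]),
             score = as.numeric(score),
             is_high = threshold_above(as.numeric(score), high_threshold),
             row.names = NULL)
}
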