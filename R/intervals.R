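#' Build non-overlapping fixed-width peaks from summits
#'
#' Summits are padded by \code{pad} bp on either side (an 801-bp window by
#' default) and processed in decreasing significance, keeping a summit iff
#' its padded window overlaps no previously kept window on the same
#' chromosome (ties broken by chromosome then position). Kept summits are
#' emitted as fixed-width peaks of \code{width} bp centred on the summit
#' (301 bp: summit - 150 to summit + 151, 0-based half-open). Overlap is
#' tested on the padded windows, before resizing. Windows running past the
#' chromosome start are clamped at 0.
#'
#' @param summits Data.frame with columns \code{chrom}, \code{summit}
#'   (0-based bp) and \code{significance} (larger = more significant).
#' @param pad Padding on either side of the summit for overlap testing.
#' @param width Final peak width (odd; the peak is summit +/- (width-1)/2).
#' @return Data.frame \code{chrom}, \code{start}, \code{end},
#'   \code{summit}, \code{significance}, sorted by chromosome and start.
#' @export
filter_summits <- function(summits, pad = 400L, width = 301L) {
  stopifnot(width %% 2L == 1L, all(summits$summit >= 0))
  half <- (width - 1L) %/% 2L
  ord <- order(-summits$significance, summits$chrom, summits$summit)
  s <- summits[ord, , drop = FALSE]
  kept <- vector("list", length(unique(s$chrom)))
  names(kept) <- unique(s$chrom)
  keep_row <- logical(nrow(s))
  for (i in seq_len(nrow(s))) {
    ch <- s$chrom[i]
    lo <- max(0L, s$summit[i] - pad)
    hi <- s$summit[i] + pad + 1L
    prev <- kept[[ch]]
    clash <- FALSE
    if (!is.null(prev) && length(prev$lo))
      clash <- any(lo < prev$hi & prev$lo < hi)
    if (!clash) {
      kept[[ch]] <- list(lo = c(prev$lo, lo), hi = c(prev$hi, hi))
      keep_row[i] <- TRUE
    }
  }
  out <- s[keep_row, , drop = FALSE]
  out$start <- pmax(0L, out$summit - half)
  out$end <- out$summit + half + 1L
  out <- out[order(out$chrom, out$start),
             c("chrom", "start", "end", "summit", "significance")]
  rownames(out) <- NULL
  out
}

#' Pseudobulk a count matrix by cell group
#'
#' Column-wise sums of raw counts over the member cells of each group,
#' with reads-per-million normalization by the group total and an
#' expression filter flag (RPM at or above \code{min_rpm} in at least one
#' group).
#'
#' @param counts Cells x features count matrix (dense or sparse).
#' @param groups Named character vector, cell to group; every group must
#'   have at least one cell with counts.
#' @param min_rpm Expression filter threshold (default 10).
#' @return A list with \code{counts} (groups x features), \code{rpm},
#'   and \code{expressed} (logical per feature).
#' @export
pseudobulk <- function(counts, groups, min_rpm = 10) {
  cells <- rownames(counts)
  g <- groups[cells]
  if (anyNA(g)) stop("every cell needs a group label")
  empty <- setdiff(unique(groups), g)
  if (length(empty)) stop("empty group(s): ", paste(empty, collapse = ", "))
  gc <- rowsum(as.matrix(counts), g)
  tot <- rowSums(gc)
  if (any(tot == 0)) stop("group with zero total counts")
  rpm <- gc / tot * 1e6
  list(counts = gc, rpm = rpm,
       expressed = apply(rpm, 2L, max) >= min_rpm)
}

#' Select variable peaks by RPM standard deviation
#'
#' Peaks with a maximum raw count of at least \code{min_raw} in some
#' sample are ranked by the standard deviation of their RPM values across
#' samples; the \code{top_n} are returned (all eligible peaks if fewer).
#'
#' @param rpm Samples x peaks RPM matrix.
#' @param raw Samples x peaks raw count matrix.
#' @param min_raw Minimum raw count in at least one sample (default 20).
#' @param top_n Number of peaks to keep (default 10000).
#' @return Character vector of peak names (or indices when unnamed),
#'   in decreasing SD order.
#' @export
variable_peaks <- function(rpm, raw, min_raw = 20L, top_n = 10000L) {
  stopifnot(dim(rpm) == dim(raw))
  eligible <- which(apply(raw, 2L, max) >= min_raw)
  sds <- col_sds(rpm[, eligible, drop = FALSE])
  ord <- eligible[order(-sds, eligible)]
  ord <- ord[seq_len(min(top_n, length(ord)))]
  if (!is.null(colnames(rpm))) colnames(rpm)[ord] else ord
}

#' Z-scores and change relative to control samples
#'
#' Per feature, values are z-scored across all samples (n - 1 SD) and the
#' change is each sample's z minus the mean z over the control samples.
#' Zero-variance features are flagged and left NA.
#'
#' @param values Samples x features numeric matrix.
#' @param control_samples Row names (or indices) of the control samples.
#' @return A list with \code{z}, \code{change} (samples x features) and
#'   \code{degenerate} (logical per feature).
#' @export
zscore_change <- function(values, control_samples) {
  values <- as.matrix(values)
  mu <- colMeans(values)
  sd <- col_sds(values)
  degenerate <- sd == 0
  z <- sweep(sweep(values, 2L, mu), 2L, ifelse(degenerate, NA, sd), "/")
  ctrl <- colMeans(z[control_samples, , drop = FALSE])
  change <- sweep(z, 2L, ctrl)
  list(z = z, change = change, degenerate = degenerate)
}
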