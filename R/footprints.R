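#' Exclude footprint bins that never reach a minimal score
#'
#' Bins whose maximum score across all conditions is below \code{min_max}
#' are removed; the remaining (peak, bin) pairs are kept for every
#' condition.
#'
#' @param footprints Data.frame with columns \code{peak},
#'   \code{bin_start}, \code{condition}, \code{score} (10-bp bins).
#' @param min_max Exclusion threshold (default 0.2; bins with maximum
#'   score below it are dropped).
#' @return The filtered footprint table.
#' @export
filter_footprint_bins <- function(footprints, min_max = 0.2) {
  key <- paste(footprints$peak, footprints$bin_start)
  mx <- tapply(footprints$score, key, max)
  keep <- names(mx)[mx >= min_max]
  footprints[key %in% keep, , drop = FALSE]
}

#' Per-condition uniform quantile transform of footprint scores
#'
#' Within each condition, scores are mapped monotonically onto their
#' empirical quantiles: a score of rank r (average rank for ties) among n
#' maps to (r - 1)/(n - 1), so the transform is rank-preserving with range
#' [0, 1].
#'
#' @param footprints Footprint table (ideally already filtered with
#'   [filter_footprint_bins()]).
#' @return The table with \code{score} replaced by its per-condition
#'   quantile.
#' @export
quantile_transform <- function(footprints) {
  for (cc in unique(footprints$condition)) {
    i <- footprints$condition == cc
    x <- footprints$score[i]
    n <- length(x)
    footprints$score[i] <- if (n > 1L) (rank(x, ties.method = "average") - 1) / (n - 1)
                           else 0.5
  }
  footprints
}

#' Call memory footprints from condition deltas
#'
#' The change at each (peak, bin) is the case-condition score minus the
#' matched-control score; sites with change at or above \code{delta_min}
#' (the threshold of 0.2 is inclusive) and attributable to a family via
#' the supplied family-site map are the family's memory sites. Midpoints
#' are bin_start + 5 bp (centre of the 10-bp bin).
#'
#' @param footprints Footprint table (raw or quantile-transformed scores;
#'   which scale the threshold applies to is the caller's choice).
#' @param sites Data.frame \code{family}, \code{peak}, \code{bin_start}:
#'   the motif occupancy map from upstream motif matching.
#' @param case,control Condition names; the pairing is explicit and never
#'   inferred.
#' @param delta_min Minimum change (inclusive, default 0.2).
#' @return A list of class \code{"memory_sites"}: one data.frame
#'   (\code{peak}, \code{bin_start}, \code{delta}, \code{midpoint}) per
#'   family, plus attribute \code{delta_table} with the change at every
#'   (peak, bin).
#' @export
call_memory_sites <- function(footprints, sites, case, control,
                              delta_min = 0.2) {
  fa <- footprints[footprints$condition == case, ]
  fb <- footprints[footprints$condition == control, ]
  key_a <- paste(fa$peak, fa$bin_start)
  key_b <- paste(fb$peak, fb$bin_start)
  common <- intersect(key_a, key_b)
  if (length(common) < length(union(key_a, key_b)))
    stop("both conditions must be present for every (peak, bin)")
  delta <- fa$score[match(common, key_a)] - fb$score[match(common, key_b)]
  dt <- data.frame(peak = fa$peak[match(common, key_a)],
                   bin_start = fa$bin_start[match(common, key_a)],
                   delta = delta, stringsAsFactors = FALSE)
  out <- lapply(split(sites, sites$family), function(ss) {
    kk <- paste(ss$peak, ss$bin_start)
    d <- dt$delta[match(kk, paste(dt$peak, dt$bin_start))]
    keep <- !is.na(d) & threshold_at_least(d, delta_min)
    data.frame(peak = ss$peak[keep], bin_start = ss$bin_start[keep],
               delta = d[keep], midpoint = ss$bin_start[keep] + 5L,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  structure(out, delta_table = dt, class = c("memory_sites", "list"))
}

#' Co-binding scores between TF families from memory-site co-occurrence
#'
#' For each pair of families, peaks are cross-tabulated by whether they
#' contain a memory site of the first family, the second, both or
#' neither; the 2x2 odds ratio (both x neither)/(first x second) is
#' log2-transformed (with a Haldane-Anscombe 0.5 added to every cell when
#' any cell is zero). Across all pairs, positive log2 values are clipped
#' to their 10th-90th percentile range and scaled linearly to [0, 1];
#' negative values likewise to [-1, 0]. When the percentile range is
#' degenerate, all values of that sign map to +/-1.
#'
#' @param memory A \code{"memory_sites"} object (or named list of
#'   data.frames with a \code{peak} column).
#' @param peak_universe Character vector of all peaks in the filtered
#'   universe.
#' @return Data.frame, one row per ordered pair: counts \code{both},
#'   \code{first_only}, \code{second_only}, \code{neither},
#'   \code{odds_ratio}, \code{log2_or}, \code{score}. Pairs involving a
#'   family with no memory sites are NA.
#' @export
cobinding_score <- function(memory, peak_universe) {
  fams <- names(memory)
  if (length(fams) < 2L) stop("need at least two families")
  member <- vapply(memory, function(m)
    peak_universe %in% unique(m$peak), logical(length(peak_universe)))
  pairs <- expand.grid(first = fams, second = fams,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$first != pairs$second, , drop = FALSE]
  res <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    a <- member[, pairs$first[r]]; b <- member[, pairs$second[r]]
    if (!any(a) || !any(b))
      return(data.frame(family1 = pairs$first[r], family2 = pairs$second[r],
                        both = NA_integer_, first_only = NA_integer_,
                        second_only = NA_integer_, neither = NA_integer_,
                        odds_ratio = NA_real_, log2_or = NA_real_))
    tb <- c(both = sum(a & b), first_only = sum(a & !b),
            second_only = sum(!a & b), neither = sum(!a & !b))
    tc <- if (any(tb == 0L)) tb + 0.5 else tb
    or <- (tc["both"] * tc["neither"]) / (tc["first_only"] * tc["second_only"])
    data.frame(family1 = pairs$first[r], family2 = pairs$second[r],
               both = tb[["both"]], first_only = tb[["first_only"]],
               second_only = tb[["second_only"]], neither = tb[["neither"]],
               odds_ratio = unname(or), log2_or = unname(log2(or)))
  }))
  rownames(res) <- NULL
  res$score <- scale_log_or(res$log2_or)
  res
}

# Clip values to the 10th-90th percentile range within each sign class and
# rescale linearly, positives to [0, 1] and negatives to [-1, 0].
# Duplicated symmetric pairs do not distort the quantiles (each value
# appears with the same multiplicity).
scale_log_or <- function(v) {
  out <- rep(NA_real_, length(v))
  out[!is.na(v) & v == 0] <- 0
  pos <- which(!is.na(v) & v > 0)
  if (length(pos)) {
    q <- stats::quantile(v[pos], c(0.1, 0.9), names = FALSE)
    out[pos] <- if (diff(q) <= 0) 1 else
      (pmin(pmax(v[pos], q[1L]), q[2L]) - q[1L]) / diff(q)
  }
  neg <- which(!is.na(v) & v < 0)
  if (length(neg)) {
    q <- stats::quantile(v[neg], c(0.1, 0.9), names = FALSE)
    out[neg] <- if (diff(q) <= 0) -1 else
      -(q[2L] - pmin(pmax(v[neg], q[1L]), q[2L])) / diff(q) - 0
  }
  out
}

#' Midpoint distances between two families' memory sites within peaks
#'
#' All pairwise absolute differences between the midpoints of the two
#' families' memory sites that share a peak. Sites in different peaks
#' contribute nothing.
#'
#' @param memory A \code{"memory_sites"} object.
#' @param family1,family2 Family names.
#' @return Numeric vector of distances in bp.
#' @export
site_distances <- function(memory, family1, family2) {
  a <- memory[[family1]]; b <- memory[[family2]]
  shared <- intersect(a$peak, b$peak)
  unlist(lapply(shared, function(pk) {
    as.vector(abs(outer(a$midpoint[a$peak == pk],
                        b$midpoint[b$peak == pk], "-")))
  }), use.names = FALSE)
}

#' Collapse overlapping motif sites within peaks
#'
#' Overlapping sites (intervals) of the same peak are merged into one
#' site carrying the largest absolute footprint change of its members.
#'
#' @param sites Data.frame \code{peak}, \code{start}, \code{end},
#'   \code{delta} (0-based half-open intervals).
#' @return Collapsed data.frame with the same columns.
#' @export
collapse_overlapping_sites <- function(sites) {
  do.call(rbind, lapply(split(sites, sites$peak), function(ss) {
    ss <- ss[order(ss$start, ss$end), , drop = FALSE]
    grp <- integer(nrow(ss)); g <- 1L; grp[1L] <- 1L
    hi <- ss$end[1L]
    for (i in seq_len(nrow(ss))[-1L]) {
      if (ss$start[i] < hi) grp[i] <- g
      else { g <- g + 1L; grp[i] <- g }
      hi <- max(hi, ss$end[i])
    }
    do.call(rbind, lapply(split(ss, grp), function(gg)
      data.frame(peak = gg$peak[1L], start = min(gg$start),
                 end = max(gg$end),
                 delta = gg$delta[which.max(abs(gg$delta))],
                 stringsAsFactors = FALSE)))
  }))
}

#' Sensitivity/specificity sweep of footprint change against binding labels
#'
#' Per-peak footprint changes (e.g. the maximum absolute change over
#' collapsed motif sites) are thresholded at every observed value;
#' predicted-positive means change >= threshold. Sensitivity and
#' specificity against binary differential-binding labels are reported
#' for each threshold, including one below the minimum (everything
#' positive).
#'
#' @param deltas Numeric vector of per-peak footprint changes.
#' @param labels Logical (or 0/1) vector of differential-binding labels.
#' @return Data.frame \code{threshold}, \code{sensitivity},
#'   \code{specificity}.
#' @export
footprint_binding_performance <- function(deltas, labels) {
  labels <- as.logical(labels)
  stopifnot(length(deltas) == length(labels))
  thr <- c(min(deltas) - 1, sort(unique(deltas)))
  pos <- sum(labels); neg <- sum(!labels)
  out <- vapply(thr, function(t) {
    pred <- deltas >= t
    c(sensitivity = if (pos) sum(pred & labels) / pos else NA_real_,
      specificity = if (neg) sum(!pred & !labels) / neg else NA_real_)
  }, numeric(2))
  data.frame(threshold = thr, sensitivity = out[1L, ],
             specificity = out[2L, ])
}
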