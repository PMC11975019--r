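#' Background-corrected deviation z-scores for annotated feature sets
#'
#' For each cell \eqn{i} and annotation set \eqn{m} (a peak set for a motif
#' family, or a weighted gene list for an expression program) the expected
#' count is \eqn{E_{im} = d_i \sum_{j \in m} w_j f_j}, where \eqn{d_i} is
#' the cell's total count and \eqn{f_j} feature \eqn{j}'s fraction of all
#' counts. The raw deviation \eqn{(o_{im} - E_{im})/E_{im}} is standardized
#' against \code{n_background} matched background sets: features are
#' grouped into \code{n_bins} equal-size bins by mean fraction, and each
#' background replicate substitutes every member by its image under an
#' independent within-bin permutation of the features. The permutation
#' scheme keeps background sets bijective with the original set, so a set
#' containing all features scores exactly zero.
#'
#' @param counts Cells x features count matrix (dense or \pkg{Matrix}
#'   sparse), raw counts.
#' @param sets Named list of annotation sets: integer/character feature
#'   indices, or lists with \code{members} and optional nonnegative
#'   \code{weights} (defaults to 1).
#' @param n_background Number of background replicates (default 250).
#' @param n_bins Number of matching bins (10 for peak accessibility,
#'   20 for gene expression programs).
#' @param seed Integer seed controlling the background permutations.
#' @return A cells x sets matrix of deviation z-scores with attributes
#'   \code{n_background}, \code{n_bins} and \code{seed}. Cells with zero
#'   expected count for a set are NA.
#' @export
deviation_scores <- function(counts, sets, n_background = 250L,
                             n_bins = 10L, seed = 1L) {
  counts <- as_csparse(counts)
  n_feat <- ncol(counts)
  if (is.null(names(sets))) names(sets) <- sprintf("set_%03d", seq_along(sets))
  sets <- lapply(sets, function(s) {
    if (is.list(s)) {
      members <- s$members
      weights <- if (is.null(s$weights)) rep(1, length(members)) else s$weights
    } else {
      members <- s
      weights <- rep(1, length(s))
    }
    if (is.character(members)) members <- match(members, colnames(counts))
    if (!length(members) || anyNA(members) ||
        any(members < 1L | members > n_feat))
      stop("annotation sets must be non-empty and within matrix bounds")
    if (any(weights < 0)) stop("weights must be nonnegative")
    list(members = as.integer(members), weights = as.numeric(weights))
  })
  depth <- Matrix::rowSums(counts)
  f <- Matrix::colSums(counts) / sum(depth)
  # equal-size bins by mean feature fraction
  bin <- ceiling(rank(f, ties.method = "first") * n_bins / n_feat)
  bin_members <- split(seq_len(n_feat), bin)
  perms <- with_seed(seed, lapply(seq_len(n_background), function(b) {
    p <- integer(n_feat)
    for (mem in bin_members) p[mem] <- if (length(mem) > 1L) sample(mem) else mem
    p
  }))
  out <- matrix(NA_real_, nrow(counts), length(sets),
                dimnames = list(rownames(counts), names(sets)))
  for (s in seq_along(sets)) {
    members <- sets[[s]]$members
    w <- sets[[s]]$weights
    m <- length(members)
    cols <- c(list(members), lapply(perms, function(p) p[members]))
    W <- Matrix::sparseMatrix(
      i = unlist(cols), j = rep.int(seq_along(cols), rep(m, length(cols))),
      x = rep.int(w, length(cols)), dims = c(n_feat, length(cols)))
    obs <- as.matrix(counts %*% W)
    ew <- as.vector(f %*% W)      # expected fraction per column
    if (ew[1L] <= 0) next         # undefined for every cell
    raw <- obs / (depth %o% ew) - 1
    raw[depth == 0, ] <- NA_real_
    bg <- raw[, -1L, drop = FALSE]
    mu <- rowMeans(bg)
    sd <- sqrt(pmax(0, rowMeans(bg^2) - mu^2) * ncol(bg) / (ncol(bg) - 1))
    z <- (raw[, 1L] - mu) / sd
    z[sd == 0 & abs(raw[, 1L] - mu) < 1e-12] <- 0
    out[, s] <- z
  }
  attr(out, "n_background") <- n_background
  attr(out, "n_bins") <- n_bins
  attr(out, "seed") <- seed
  out
}

#' Bag motifs into families by similarity, led by the most variable
#'
#' Motifs are sorted by decreasing cross-cell variability; each motif in
#' turn joins the first existing leader to which its similarity q-value is
#' at or below \code{q_threshold}, otherwise it founds a new family.
#' Similarity may be reported in one direction only; the minimum of the
#' two directions is used and missing pairs count as dissimilar (q = 1).
#'
#' @param variability Named numeric vector of per-motif variability (e.g.
#'   the standard deviation of deviation scores across cells), or a
#'   cells x motifs score matrix from which column SDs are taken.
#' @param similarity_q Data.frame with columns \code{motif1},
#'   \code{motif2}, \code{q}, or a square named matrix of q-values.
#' @param q_threshold Merge threshold (inclusive; q of exactly 0.05
#'   merges).
#' @return A list with \code{assignment} (data.frame motif, leader,
#'   variability), \code{families} (named list, leader to members) and
#'   \code{leaders}.
#' @export
bag_motif_families <- function(variability, similarity_q,
                               q_threshold = 0.05) {
  if (is.matrix(variability)) variability <- col_sds(variability)
  motifs <- names(variability)
  Q <- matrix(1, length(motifs), length(motifs),
              dimnames = list(motifs, motifs))
  if (is.data.frame(similarity_q)) {
    for (r in seq_len(nrow(similarity_q))) {
      a <- as.character(similarity_q$motif1[r])
      b <- as.character(similarity_q$motif2[r])
      if (a %in% motifs && b %in% motifs) {
        q <- min(Q[a, b], similarity_q$q[r])
        Q[a, b] <- q; Q[b, a] <- q
      }
    }
  } else {
    common <- intersect(motifs, rownames(similarity_q))
    Q[common, common] <- pmin(Q[common, common],
                              similarity_q[common, common],
                              t(similarity_q[common, common]))
  }
  ord <- motifs[order(-variability, motifs)]
  leaders <- character(0)
  leader_of <- stats::setNames(character(length(motifs)), motifs)
  for (m in ord) {
    hit <- leaders[Q[m, leaders] <= q_threshold][1L]
    if (!is.na(hit) && length(hit)) leader_of[m] <- hit
    else { leaders <- c(leaders, m); leader_of[m] <- m }
  }
  assignment <- data.frame(motif = motifs, leader = leader_of[motifs],
                           variability = as.numeric(variability),
                           stringsAsFactors = FALSE, row.names = NULL)
  list(assignment = assignment,
       families = split(assignment$motif, assignment$leader),
       leaders = leaders)
}

#' Per-sample score summaries and condition tests
#'
#' Single-cell scores are averaged within each sample; change is the
#' difference between a sample's mean and the average of the control
#' samples' means. For the \code{top_n} most variable families (by SD of
#' per-sample means) a two-sided Welch t-test compares each non-control
#' condition's sample means against the control's, with
#' Benjamini-Hochberg adjustment across the tested families within each
#' condition. Samples with fewer than \code{min_cells} cells are flagged
#' (kept in the statistics, flagged for exclusion from display).
#'
#' @param scores Cells x families score matrix.
#' @param cell_sample Named character vector, cell to sample.
#' @param sample_condition Named character vector, sample to condition.
#' @param control Name of the control condition.
#' @param top_n Number of most-variable families tested.
#' @param min_cells Flagging threshold for small samples.
#' @return A list with \code{sample_means}, \code{change} (samples x
#'   families), \code{tests} (family, condition, p, q), \code{top_families}
#'   and \code{flagged_samples}.
#' @export
per_sample_stats <- function(scores, cell_sample, sample_condition,
                             control = "control", top_n = 50L,
                             min_cells = 200L) {
  cells <- rownames(scores)
  samp <- cell_sample[cells]
  if (anyNA(samp)) stop("every scored cell needs a sample label")
  n_per <- table(samp)
  sample_means <- rowsum(scores, samp) / as.vector(n_per[sort(unique(samp))])
  control_samples <- rownames(sample_means)[
    sample_condition[rownames(sample_means)] == control]
  if (!length(control_samples)) stop("no control samples present")
  ctrl_mean <- colMeans(sample_means[control_samples, , drop = FALSE])
  change <- sweep(sample_means, 2L, ctrl_mean)
  variability <- col_sds(sample_means)
  top <- colnames(scores)[order(-variability,
                                seq_len(ncol(scores)))][
                                  seq_len(min(top_n, ncol(scores)))]
  conds <- setdiff(unique(sample_condition[rownames(sample_means)]), control)
  tests <- do.call(rbind, lapply(conds, function(cc) {
    cc_samples <- rownames(sample_means)[
      sample_condition[rownames(sample_means)] == cc]
    p <- vapply(top, function(fam) {
      x <- sample_means[cc_samples, fam]
      y <- sample_means[control_samples, fam]
      if (length(x) < 2L || length(y) < 2L) return(NA_real_)
      stats::t.test(x, y)$p.value
    }, numeric(1))
    data.frame(family = top, condition = cc, p = p,
               q = stats::p.adjust(p, "BH"),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  list(sample_means = sample_means, change = change, tests = tests,
       top_families = top,
       flagged_samples = names(n_per)[n_per < min_cells])
}

#' Fraction of activated cells per sample
#'
#' Activated cells are those with a score strictly greater than
#' \code{threshold} (default 1.5); a score of exactly 1.5 is not activated.
#'
#' @param scores Numeric vector of per-cell scores for one family.
#' @param cell_sample Named character vector, cell to sample; defaults to a
#'   single pooled sample.
#' @param threshold Activation threshold (exclusive).
#' @return Named numeric vector of per-sample activated fractions.
#' @export
activated_fraction <- function(scores, cell_sample = NULL, threshold = 1.5) {
  if (is.null(cell_sample))
    return(c(all = mean(threshold_above(scores, threshold), na.rm = TRUE)))
  samp <- cell_sample[names(scores)]
  out <- tapply(scores, samp, function(x) mean(threshold_above(x, threshold), na.rm = TRUE))
  stats::setNames(as.numeric(out), names(out))
}

#' Kolmogorov-Smirnov heterogeneity test between two conditions
#'
#' Each condition is randomly downsampled to \code{n_downsample} cells
#' (all cells are used, with a flag, when fewer are available) and a
#' two-sample KS test compares the score distributions.
#'
#' @param scores Numeric vector of per-cell scores.
#' @param condition Character vector of per-cell condition labels, parallel
#'   to \code{scores}.
#' @param cond_a,cond_b The two conditions to compare.
#' @param n_downsample Cells retained per condition.
#' @param seed Integer seed; the same seed is applied to each condition's
#'   draw, so identical condition vectors yield identical samples.
#' @return A list with \code{p}, \code{statistic}, \code{n} (per-condition
#'   sizes used) and \code{downsampled} (logical per condition).
#' @export
heterogeneity_test <- function(scores, condition, cond_a, cond_b,
                               n_downsample = 500L, seed = 1L) {
  take <- function(cc) {
    x <- scores[condition == cc]
    if (length(x) > n_downsample)
      list(x = with_seed(seed, x[sample(length(x), n_downsample)]),
           down = TRUE)
    else list(x = x, down = FALSE)
  }
  a <- take(cond_a); b <- take(cond_b)
  kt <- suppressWarnings(stats::ks.test(a$x, b$x))
  list(p = kt$p.value, statistic = unname(kt$statistic),
       n = c(length(a$x), length(b$x)),
       downsampled = c(a$down, b$down))
}
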