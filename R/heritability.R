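#' Clonal variance of a per-cell score
#'
#' The within-clone standard deviation (n - 1 denominator) is computed for
#' every clone with at least \code{min_cells} cells, and the clonal
#' variance is the median of these SDs across clones, squared.
#'
#' @param scores Numeric vector of per-cell scores.
#' @param clone Clone labels, parallel to \code{scores}.
#' @param min_cells Minimum cells for a clone to contribute (default 2,
#'   the smallest size with a defined SD).
#' @return The clonal variance (nonnegative scalar).
#' @export
clonal_variance <- function(scores, clone, min_cells = 2L) {
  sds <- tapply(scores, clone, stats::sd)
  n <- tapply(scores, clone, length)
  sds <- sds[n >= min_cells]
  if (!length(sds)) stop("no clone has at least ", min_cells, " cells")
  stats::median(sds)^2
}

#' Permutation test for clonal heritability of single-cell scores
#'
#' For every feature the observed clonal variance (see [clonal_variance()])
#' is compared with its null distribution under random reassignment of
#' cells to clones: cell-clone labels are permuted \code{n_perm} times
#' (clone sizes preserved; the same permutations are shared by all
#' features) and the statistic recomputed. The normal approximation gives
#' \deqn{Z = (obs - mean_{shuffled}) / sd_{shuffled}, \quad
#'       p = 2\Phi(-|Z|),}
#' with Benjamini-Hochberg adjustment across features. Heritable features
#' have within-clone SDs below the shuffled expectation, hence negative Z.
#' An exact rank-based permutation p-value is reported alongside as a
#' diagnostic for skewed nulls. Features whose shuffled statistic is
#' constant are flagged degenerate with p = 1.
#'
#' @param scores Cells x features numeric matrix (or a vector for a single
#'   feature).
#' @param clone Clone labels per cell.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the shared permutations.
#' @param min_cells Minimum cells per clone for the statistic.
#' @return An object of class \code{"clonal_heritability"}: a list with
#'   \code{results} (data.frame feature, observed, mean_shuffled,
#'   sd_shuffled, Z, p, p_empirical, fdr, degenerate), \code{n_perm},
#'   \code{seed} and \code{clone_sizes}.
#' @export
clonal_heritability <- function(scores, clone, n_perm = 1000L, seed = 1L,
                                min_cells = 2L) {
  if (is.null(dim(scores)))
    scores <- matrix(scores, ncol = 1L, dimnames = list(names(scores), "score"))
  scores <- as.matrix(scores)
  if (!all(is.finite(scores))) stop("scores must be finite")
  clone <- as.character(clone)
  if (length(clone) != nrow(scores))
    stop("clone labels must match rows of scores")
  if (anyNA(clone)) {
    # cells without a clone assignment carry no lineage information
    warning(sum(is.na(clone)), " cells without clone labels dropped")
    scores <- scores[!is.na(clone), , drop = FALSE]
    clone <- clone[!is.na(clone)]
  }
  if (length(unique(clone)) < 2L) {
    # a single clone is invariant under permutation: everything degenerate
    obs <- apply(scores, 2L, clonal_variance, clone = clone,
                 min_cells = min_cells)
    res <- data.frame(feature = colnames(scores), observed = obs,
                      mean_shuffled = obs, sd_shuffled = 0, Z = NA_real_,
                      p = 1, p_empirical = 1, fdr = 1, degenerate = TRUE,
                      stringsAsFactors = FALSE, row.names = NULL)
    return(structure(list(results = res, n_perm = n_perm, seed = seed,
                          clone_sizes = table(clone)),
                     class = "clonal_heritability"))
  }
  stat <- function(g) {
    sds <- group_sds(scores, g)
    keep <- !is.na(sds[, 1L])
    col_medians(sds[keep, , drop = FALSE])^2
  }
  obs <- stat(clone)
  n <- nrow(scores)
  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) stat(clone[sample(n)]),
           numeric(ncol(scores)))
  })
  perm_stats <- if (is.null(dim(perm_stats)))
    matrix(perm_stats, ncol = 1L) else t(perm_stats)
  mu <- colMeans(perm_stats)
  sd <- col_sds(perm_stats)
  Z <- (obs - mu) / sd
  p <- 2 * stats::pnorm(-abs(Z))
  degenerate <- sd == 0
  Z[degenerate] <- NA_real_
  p[degenerate] <- 1
  ge <- colSums(perm_stats >= rep(obs, each = n_perm))
  le <- colSums(perm_stats <= rep(obs, each = n_perm))
  p_emp <- pmin(1, 2 * (pmin(ge, le) + 1) / (n_perm + 1))
  res <- data.frame(feature = colnames(scores), observed = obs,
                    mean_shuffled = mu, sd_shuffled = sd, Z = Z, p = p,
                    p_empirical = p_emp,
                    fdr = stats::p.adjust(p, "BH"),
                    degenerate = degenerate,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(results = res, n_perm = n_perm, seed = seed,
                 clone_sizes = table(clone)),
            class = "clonal_heritability")
}

#' @export
print.clonal_heritability <- function(x, ...) {
  cat("Clonal heritability permutation test\n")
  cat("  features:", nrow(x$results), "  clones:", length(x$clone_sizes),
      "  permutations:", x$n_perm, "\n")
  cat("  significant at FDR < 0.05:",
      sum(x$results$fdr < 0.05, na.rm = TRUE), "\n")
  invisible(x)
}

#' @export
summary.clonal_heritability <- function(object, fdr = 0.05, ...) {
  res <- object$results
  hits <- res[!is.na(res$fdr) & res$fdr < fdr, , drop = FALSE]
  hits <- hits[order(hits$fdr, hits$p), , drop = FALSE]
  out <- list(n_features = nrow(res), n_significant = nrow(hits),
              n_degenerate = sum(res$degenerate), fdr = fdr, hits = hits)
  class(out) <- "summary.clonal_heritability"
  out
}

#' @export
print.summary.clonal_heritability <- function(x, ...) {
  cat("Clonal heritability:", x$n_significant, "of", x$n_features,
      "features at FDR <", x$fdr, "\n")
  if (x$n_degenerate) cat("  degenerate features:", x$n_degenerate, "\n")
  if (nrow(x$hits)) {
    cat("Top features:\n")
    print(utils::head(x$hits[, c("feature", "observed", "Z", "p", "fdr")], 10L),
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.clonal_heritability <- function(x, ...) {
  res <- x$results[!x$results$degenerate, ]
  graphics::plot(res$Z, -log10(pmax(res$p, 1e-300)),
                 xlab = "Z (observed vs shuffled clonal variance)",
                 ylab = "-log10 p", pch = 16,
                 col = ifelse(res$fdr < 0.05, "firebrick", "grey40"), ...)
  graphics::abline(h = -log10(0.05), lty = 2)
  invisible(x)
}

#' @export
as.data.frame.clonal_heritability <- function(x, ...) x$results

#' Compare clone-level score distributions between conditions
#'
#' Summarizes each clone by the median and standard deviation of its
#' cells' scores, then compares conditions: a two-sample KS test on the
#' per-clone SDs, the case-minus-control shift of the median clone median
#' and median clone SD, and the per-condition fraction of clones whose
#' median score is strictly above \code{high_threshold}.
#'
#' @param scores Numeric vector of per-cell scores.
#' @param clone Clone labels per cell.
#' @param clone_condition Named character vector, clone to condition.
#' @param case,control Condition names.
#' @param high_threshold High-clone threshold on the clone median
#'   (exclusive; default 1.25).
#' @param min_clones Minimum clones per condition.
#' @return A list with \code{summaries} (data.frame clone, condition,
#'   n_cells, median_score, sd_score), \code{ks_p}, \code{median_shift},
#'   \code{sd_shift} and \code{high_fraction} (named per condition).
#' @export
compare_clone_distributions <- function(scores, clone, clone_condition,
                                        case, control,
                                        high_threshold = 1.25,
                                        min_clones = 3L) {
  med <- tapply(scores, clone, stats::median)
  sds <- tapply(scores, clone, stats::sd)
  n <- tapply(scores, clone, length)
  summaries <- data.frame(clone = names(med),
                          condition = clone_condition[names(med)],
                          n_cells = as.integer(n),
                          median_score = as.numeric(med),
                          sd_score = as.numeric(sds),
                          stringsAsFactors = FALSE, row.names = NULL)
  sub <- function(cc) summaries[summaries$condition == cc, , drop = FALSE]
  a <- sub(case); b <- sub(control)
  if (nrow(a) < min_clones || nrow(b) < min_clones)
    stop("need at least ", min_clones, " clones per condition")
  ks <- suppressWarnings(stats::ks.test(a$sd_score, b$sd_score))
  high <- vapply(unique(summaries$condition), function(cc)
    mean(threshold_above(sub(cc)$median_score, high_threshold)), numeric(1))
  list(summaries = summaries,
       ks_p = ks$p.value,
       median_shift = stats::median(a$median_score) -
         stats::median(b$median_score),
       sd_shift = stats::median(a$sd_score) - stats::median(b$sd_score),
       high_fraction = high)
}

#' Correlate motif and gene-program scores across clones
#'
#' The mean of each motif score and each program score is computed per
#' clone; Pearson correlations of the clone-mean vectors are returned for
#' every motif-program pair, with the best-correlated program per motif.
#'
#' @param motif_scores Cells x motifs score matrix.
#' @param program_scores Cells x programs score matrix (same cells).
#' @param clone Clone labels per cell.
#' @param method Correlation method, \code{"pearson"} (default) or
#'   \code{"spearman"}.
#' @param min_clones Minimum number of clones required.
#' @return A list with \code{cor} (motifs x programs matrix; NA where a
#'   clone-mean vector has zero variance) and \code{top_program} (named
#'   character vector, motif to best program).
#' @export
correlate_motifs_programs <- function(motif_scores, program_scores, clone,
                                      method = c("pearson", "spearman"),
                                      min_clones = 3L) {
  method <- match.arg(method)
  stopifnot(nrow(motif_scores) == nrow(program_scores))
  g <- as.factor(clone)
  if (nlevels(g) < min_clones)
    stop("need at least ", min_clones, " clones")
  sizes <- as.vector(table(g))
  mmean <- rowsum(as.matrix(motif_scores), g) / sizes
  pmean <- rowsum(as.matrix(program_scores), g) / sizes
  cc <- suppressWarnings(stats::cor(mmean, pmean, method = method))
  cc[!is.finite(cc)] <- NA_real_
  top <- apply(cc, 1L, function(r)
    if (all(is.na(r))) NA_character_ else colnames(cc)[which.max(r)])
  list(cor = cc, top_program = top)
}
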