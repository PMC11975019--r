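#' Fit gene expression programs by latent Dirichlet allocation
#'
#' Raw (unnormalized, unbinarized) cell-by-gene counts are modeled with
#' LDA via a collapsed Gibbs sampler, once per candidate topic number; the
#' model with the highest log-likelihood of the observed counts is
#' selected. Topic-by-gene and cell-by-topic distributions are smoothed
#' maximum-a-posteriori estimates from the final sampler state.
#'
#' The default topic range 5..15 is a desk-scale setting for simulated
#' matrices; genome-scale analyses use ranges such as 30..90.
#'
#' @param counts Cells x genes raw count matrix (dense or sparse).
#' @param topics Integer vector of candidate topic numbers.
#' @param n_iter Gibbs sweeps per fit.
#' @param alpha,beta Dirichlet hyperparameters; \code{alpha = NULL} uses
#'   the common 50/K heuristic.
#' @param seed Integer seed.
#' @return An object of class \code{"gene_programs"}: \code{topic_gene}
#'   (K x genes, rows sum to 1), \code{cell_topic} (cells x K, rows sum to
#'   1), \code{k} (chosen topic number), \code{loglik} (named per candidate)
#'   and \code{dropped_cells}.
#' @export
fit_gene_programs <- function(counts, topics = 5:15, n_iter = 150L,
                              alpha = NULL, beta = 0.1, seed = 1L) {
  stopifnot(length(topics) >= 1L, all(topics >= 2L))
  counts <- methods::as(as_csparse(counts), "TsparseMatrix")
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stop("counts must be raw nonnegative integers")
  depth <- Matrix::rowSums(counts)
  dropped <- rownames(counts)[depth == 0]
  if (length(dropped)) {
    warning(length(dropped), " all-zero cells dropped")
    counts <- counts[depth > 0, , drop = FALSE]
    counts <- methods::as(counts, "TsparseMatrix")
  }
  doc <- counts@i + 1L
  word <- counts@j + 1L
  cnt <- as.integer(counts@x)
  n_docs <- nrow(counts); n_genes <- ncol(counts)

  fits <- vector("list", length(topics))
  loglik <- stats::setNames(numeric(length(topics)), as.character(topics))
  for (t in seq_along(topics)) {
    K <- as.integer(topics[t])
    a <- if (is.null(alpha)) 50 / K else alpha
    st <- with_seed(derive_seed(seed, 100L + K),
                    lda_gibbs(doc, word, cnt, n_docs, n_genes, K, n_iter,
                              a, beta))
    phi <- (st$n_kw + beta) / (rowSums(st$n_kw) + n_genes * beta)
    theta <- (st$n_dk + a) / (rowSums(st$n_dk) + K * a)
    # collapsed log-likelihood log P(w, z | alpha, beta) of the final
    # Gibbs state; penalizes surplus topics, unlike the training-data
    # likelihood of the point estimates
    loglik[t] <-
      K * (lgamma(n_genes * beta) - n_genes * lgamma(beta)) +
      sum(lgamma(st$n_kw + beta)) - sum(lgamma(rowSums(st$n_kw) + n_genes * beta)) +
      n_docs * (lgamma(K * a) - K * lgamma(a)) +
      sum(lgamma(st$n_dk + a)) - sum(lgamma(rowSums(st$n_dk) + K * a))
    fits[[t]] <- list(phi = phi, theta = theta)
  }
  best <- which.max(loglik)
  K <- as.integer(topics[best])
  phi <- fits[[best]]$phi
  theta <- fits[[best]]$theta
  dimnames(phi) <- list(sprintf("program_%02d", seq_len(K)), colnames(counts))
  dimnames(theta) <- list(rownames(counts), rownames(phi))
  structure(list(topic_gene = phi, cell_topic = theta, k = K,
                 loglik = loglik, dropped_cells = dropped),
            class = "gene_programs")
}

#' @export
print.gene_programs <- function(x, ...) {
  cat("Gene programs: LDA with", x$k, "topics over", ncol(x$topic_gene),
      "genes and", nrow(x$cell_topic), "cells\n")
  cat("  log-likelihood by topic number:\n")
  print(round(x$loglik))
  invisible(x)
}

#' Top genes of a program
#'
#' Genes ranked by descending topic weight; ties are broken by gene index.
#'
#' @param topic_gene A topic-by-gene matrix (e.g. from
#'   [fit_gene_programs()]) or a single named weight vector.
#' @param program Program (row) to extract when a matrix is given.
#' @param top_n Number of genes (default 150); clamped to the number of
#'   genes available.
#' @return Character vector of gene names, best first.
#' @export
program_gene_lists <- function(topic_gene, program = 1L, top_n = 150L) {
  w <- if (is.matrix(topic_gene)) topic_gene[program, ] else topic_gene
  ord <- order(-w, seq_along(w))
  names(w)[ord][seq_len(min(top_n, length(w)))]
}

#' Convert gene programs to weighted annotation sets
#'
#' Each program becomes a weighted gene set (weights = topic-gene
#' probabilities) suitable for [deviation_scores()] with 20 expression
#' bins, so cells (or tumor pseudobulks) can be scored on programs with
#' the same background-corrected machinery as motif families.
#'
#' @param programs A \code{"gene_programs"} object or topic-by-gene matrix.
#' @return Named list of \code{list(members, weights)} sets.
#' @export
programs_as_sets <- function(programs) {
  phi <- if (inherits(programs, "gene_programs")) programs$topic_gene
         else programs
  sets <- lapply(seq_len(nrow(phi)), function(k)
    list(members = colnames(phi), weights = as.numeric(phi[k, ])))
  stats::setNames(sets, rownames(phi))
}
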