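# Independent brute-force oracles used by unit and acceptance tests.

# Naive clonal variance: explicit loops, no shared code with the package.
naive_clonal_variance <- function(scores, clone) {
  sds <- c()
  for (cl in unique(clone)) {
    x <- scores[clone == cl]
    if (length(x) >= 2) sds <- c(sds, stats::sd(x))
  }
  stats::median(sds)^2
}

# Naive greedy summit filter: keep summits in decreasing significance when
# the padded window overlaps nothing kept so far (same chromosome).
naive_filter_summits <- function(summits, pad = 400, width = 301) {
  half <- (width - 1) / 2
  ord <- order(-summits$significance, summits$chrom, summits$summit)
  s <- summits[ord, ]
  kept <- s[0, ]
  for (i in seq_len(nrow(s))) {
    lo <- max(0, s$summit[i] - pad); hi <- s$summit[i] + pad + 1
    ok <- TRUE
    if (nrow(kept)) {
      same <- kept[kept$chrom == s$chrom[i], ]
      for (j in seq_len(nrow(same))) {
        jlo <- max(0, same$summit[j] - pad); jhi <- same$summit[j] + pad + 1
        if (lo < jhi && jlo < hi) { ok <- FALSE; break }
      }
    }
    if (ok) kept <- rbind(kept, s[i, ])
  }
  kept$start <- pmax(0, kept$summit - half)
  kept$end <- kept$summit + half + 1
  kept[order(kept$chrom, kept$start), c("chrom", "start", "end", "summit",
                                        "significance")]
}

# Naive k-NN average (self included), quadratic scan.
naive_knn_smooth <- function(values, coords, k) {
  n <- nrow(coords)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt(rowSums((coords - matrix(coords[i, ], n, ncol(coords),
                                       byrow = TRUE))^2))
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(k)]
    out[i] <- mean(c(values[i], values[nb]))
  }
  out
}

# All distinct cell-to-clone assignments preserving the clone-size
# multiset, for exhaustive permutation nulls on tiny instances.
enumerate_assignments <- function(clone) {
  n <- length(clone)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      rest <- perms(v[-i])
      out <- c(out, lapply(rest, function(r) c(v[i], r)))
    }
    out
  }
  unique(perms(clone))
}

# Match called tumor ids to true tumor ids by majority overlap.
match_tumors <- function(called, truth) {
  sapply(sort(unique(called)), function(id) {
    tt <- truth[called == id]
    as.integer(names(sort(-table(tt)))[1])
  })
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
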