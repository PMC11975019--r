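# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation so each generator consumes an
# independent stream from one master seed. Kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(offset)) %% 2147483587)
}

# Threshold comparisons, kept in one place because the decision
# boundaries differ: "minimum value of t" thresholds are inclusive,
# "greater than t" thresholds are strict.
threshold_at_least <- function(x, t) x >= t
threshold_above <- function(x, t) x > t

# Coerce dense or sparse input to a column-compressed sparse matrix.
as_csparse <- function(x) {
  if (methods::is(x, "CsparseMatrix")) return(x)
  methods::as(Matrix::Matrix(as.matrix(x), sparse = TRUE), "CsparseMatrix")
}

# Exact k nearest neighbours (self excluded) under Euclidean distance.
# Ties at identical distance are broken by point index, so results are
# reproducible. Returns an n x k integer matrix of neighbour indices.
knn_indices <- function(coords, k, chunk = 512L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k >= n) stop("k must be smaller than the number of points")
  sq <- rowSums(coords^2)
  out <- matrix(0L, n, k)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    idx <- lo:hi
    # squared distances chunk x n
    d2 <- outer(sq[idx], sq, "+") -
      2 * tcrossprod(coords[idx, , drop = FALSE], coords)
    for (r in seq_along(idx)) {
      i <- idx[r]
      dv <- d2[r, ]
      dv[i] <- Inf
      out[i, ] <- order(dv, seq_len(n))[seq_len(k)]
    }
  }
  out
}

# Column standard deviations (n - 1 denominator) of a dense matrix.
col_sds <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(rep(NA_real_, ncol(x)))
  mu <- colMeans(x)
  stats::setNames(sqrt(pmax(0, (colSums(x^2) - n * mu^2) / (n - 1))),
                  colnames(x))
}

# Within-group standard deviations of every column of `x`.
# Returns a groups x columns matrix; groups with < 2 members are NA.
group_sds <- function(x, g) {
  g <- as.factor(g)
  n <- as.vector(table(g))
  s1 <- rowsum(x, g)
  s2 <- rowsum(x * x, g)
  v <- (s2 - s1^2 / n) / (n - 1)
  v[v < 0] <- 0
  sd <- sqrt(v)
  sd[n < 2L, ] <- NA_real_
  sd
}

# Column-wise medians (compiled; interpolating for even counts).
col_medians <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("no rows to take medians over")
  col_medians_cpp(x)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# Apply independent per-base substitutions at rate `rate` to each sequence.
mutate_sequences <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  hit <- which(stats::runif(length(flat)) < rate)
  if (length(hit)) {
    # substitute with one of the three other bases
    cur <- flat[hit]
    repl <- bases[(match(cur, bases) - 1L + sample(1:3, length(hit), replace = TRUE)) %% 4L + 1L]
    flat[hit] <- repl
  }
  grp <- rep.int(seq_along(lens), lens)
  vapply(split(flat, grp), paste, character(1), collapse = "")
}
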