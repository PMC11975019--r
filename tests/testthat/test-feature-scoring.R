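sim_small <- simulate_counts_and_annotations(
  n_cells = 300, n_peaks = 600, n_families = 3, family_size = 60,
  effect_fold = 2, frac_affected = 0.3, seed = 41)

test_that("a set of all features scores exactly zero", {
  sc <- deviation_scores(sim_small$counts, list(all = seq_len(600)),
                         n_background = 50, seed = 1)
  expect_true(all(sc == 0))
})

test_that("scores are reproducible under the seed and depth-insensitive", {
  a <- deviation_scores(sim_small$counts, sim_small$annotations,
                        n_background = 100, seed = 3)
  b <- deviation_scores(sim_small$counts, sim_small$annotations,
                        n_background = 100, seed = 3)
  expect_identical(a, b)
  d <- Matrix::rowSums(sim_small$counts)
  # families B and C carry no planted effect: depth correlation is noise
  for (fam in c("family_B", "family_C"))
    expect_lt(abs(stats::cor(d, a[, fam])), 0.15)
})

test_that("permuted annotations give null-centred scores", {
  set.seed(5)
  perm_sets <- lapply(sim_small$annotations, function(s)
    sample(600, length(s)))
  sc <- deviation_scores(sim_small$counts, perm_sets, n_background = 100,
                         seed = 5)
  for (j in seq_len(ncol(sc))) {
    se <- stats::sd(sc[, j]) / sqrt(nrow(sc))
    expect_lt(abs(mean(sc[, j])), 3.5 * se + 0.02)
  }
})

test_that("a planted accessibility fold is detected across conditions", {
  sc <- deviation_scores(sim_small$counts, sim_small$annotations,
                         n_background = 100, seed = 7)
  aff <- rownames(sc) %in% sim_small$truth$affected_cells
  tt <- stats::t.test(sc[aff, "family_A"], sc[!aff, "family_A"],
                      alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("weighted sets reuse the same machinery", {
  w <- stats::runif(60)
  sc <- deviation_scores(sim_small$counts,
                         list(wset = list(members = sim_small$annotations[[1]],
                                          weights = w)),
                         n_background = 50, seed = 2)
  expect_true(all(is.finite(sc)))
  expect_error(deviation_scores(sim_small$counts,
                                list(bad = list(members = 1:3,
                                                weights = c(-1, 1, 1)))),
               "nonnegative")
  expect_error(deviation_scores(sim_small$counts, list(bad = 601L)),
               "bounds")
})

test_that("motif bagging follows greedy leader merging", {
  vars <- c(A = 3, B = 2, C = 1)
  q <- data.frame(motif1 = c("A", "A", "B"), motif2 = c("B", "C", "C"),
                  q = c(0.01, 0.9, 0.01))
  out <- bag_motif_families(vars, q)
  expect_identical(out$families, list(A = c("A", "B"), C = "C"))

  all_far <- data.frame(motif1 = "A", motif2 = "B", q = 1)
  out2 <- bag_motif_families(vars, all_far)
  expect_identical(lengths(out2$families), c(A = 1L, B = 1L, C = 1L))

  # threshold is inclusive at 0.05
  for (qv in c(0.049, 0.05, 0.051)) {
    o <- bag_motif_families(c(A = 2, B = 1),
                            data.frame(motif1 = "A", motif2 = "B", q = qv))
    expect_identical(length(o$families) == 1L, qv <= 0.05)
  }
  # bagging is a partition
  expect_setequal(unlist(out$families), names(vars))
})

test_that("per-sample stats centre control changes at zero", {
  set.seed(9)
  n <- 400
  cells <- sprintf("c%03d", 1:n)
  scores <- matrix(rnorm(n * 4), n, 4,
                   dimnames = list(cells, paste0("fam", 1:4)))
  scores[, 1] <- scores[, 1] +
    rep(c(0, 1), each = n / 2)          # planted condition shift on fam1
  samp <- stats::setNames(rep(sprintf("s%d", 1:8), each = n / 8), cells)
  cond <- stats::setNames(rep(c("control", "colitis"), each = 4),
                          sprintf("s%d", 1:8))
  out <- per_sample_stats(scores, samp, cond, top_n = 4, min_cells = 10)
  ctrl <- names(cond)[cond == "control"]
  expect_lt(max(abs(colMeans(out$change[ctrl, ]))), 1e-12)
  expect_lt(out$tests$q[out$tests$family == "fam1"], 0.05)
  expect_gt(min(out$tests$q[out$tests$family != "fam1"]), 0.05)
  expect_length(out$flagged_samples, 0)
  out2 <- per_sample_stats(scores, samp, cond, top_n = 4, min_cells = 60)
  expect_length(out2$flagged_samples, 8)
})

test_that("t-test p is missing when a condition has one sample", {
  set.seed(10)
  cells <- sprintf("c%02d", 1:30)
  scores <- matrix(rnorm(30), 30, 1, dimnames = list(cells, "fam"))
  samp <- stats::setNames(rep(c("s1", "s2", "s3"), each = 10), cells)
  cond <- c(s1 = "control", s2 = "control", s3 = "colitis")
  out <- per_sample_stats(scores, samp, cond, top_n = 1)
  expect_true(is.na(out$tests$p))
})

test_that("activated fraction uses a strict threshold", {
  expect_equal(unname(activated_fraction(c(2.0, 1.0, 1.6, -0.5))), 0.5)
  expect_equal(unname(activated_fraction(c(1.5, 1.5))), 0)
  set.seed(11)
  x <- rnorm(10000)
  frac <- unname(activated_fraction(x))
  expect_lt(abs(frac - stats::pnorm(-1.5)), 3 * sqrt(0.0668 * 0.9332 / 10000))
})

test_that("heterogeneity test is exact on identical downsamples", {
  set.seed(12)
  x <- rnorm(2000)
  scores <- c(x, x)
  cond <- rep(c("a", "b"), each = 2000)
  out <- heterogeneity_test(scores, cond, "a", "b", seed = 99)
  expect_equal(out$p, 1)
  expect_true(all(out$downsampled))
  # a shifted subpopulation is detected
  y <- x
  y[1:400] <- y[1:400] + 3          # 20% of cells shifted by +3 SD
  out2 <- heterogeneity_test(c(x, y), cond, "a", "b", seed = 99)
  expect_lt(out2$p, 0.01)
  # fewer cells than the downsample target: all used, flagged
  out3 <- heterogeneity_test(rnorm(100), rep(c("a", "b"), 50), "a", "b")
  expect_false(any(out3$downsampled))
})

test_that("program gene lists are a descending-weight sort", {
  expect_identical(program_gene_lists(c(g1 = 0.5, g2 = 0.3, g3 = 0.2),
                                      top_n = 2), c("g1", "g2"))
  expect_length(program_gene_lists(c(a = 1, b = 2), top_n = 10), 2)
  set.seed(13)
  for (i in 1:100) {
    w <- stats::setNames(stats::runif(20), sprintf("g%02d", 1:20))
    expect_identical(program_gene_lists(w, top_n = 5),
                     names(sort(-w))[1:5])
  }
})

test_that("LDA recovers planted topics and normalizes distributions", {
  set.seed(14)
  K <- 4; G <- 120; N <- 120
  phi <- matrix(0, K, G)
  for (k in seq_len(K)) phi[k, ((k - 1) * 30 + 1):(k * 30)] <- 1 / 30
  theta <- t(stats::rmultinom(N, 1, rep(1 / K, K))) * 0.8 + 0.05
  counts <- t(vapply(seq_len(N), function(i)
    stats::rmultinom(1, 300, colSums(theta[i, ] * phi))[, 1], numeric(G)))
  dimnames(counts) <- list(sprintf("c%03d", 1:N), sprintf("g%03d", 1:G))
  gp <- fit_gene_programs(counts, topics = c(3, 4, 6), n_iter = 150,
                          seed = 15)
  expect_identical(gp$k, 4L)
  expect_lt(max(abs(rowSums(gp$topic_gene) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(gp$cell_topic) - 1)), 1e-9)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  best <- apply(phi, 1, function(p)
    max(apply(gp$topic_gene, 1, cosine, b = p)))
  expect_true(all(best >= 0.8))
  # all-zero cells are dropped with a warning
  counts0 <- rbind(counts, zero = 0L)
  expect_warning(gp0 <- fit_gene_programs(counts0, topics = 3, n_iter = 10,
                                          seed = 1), "dropped")
  expect_identical(gp0$dropped_cells, "zero")
})
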