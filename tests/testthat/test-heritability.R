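test_that("clonal variance matches hand computation and a naive oracle", {
  expect_equal(clonal_variance(c(5, 5, 5, 5), c("A", "A", "B", "B")), 0)
  # clones A=[1,1], B=[0,2]: SDs 0 and sqrt(2), median 0.7071, squared 0.5
  expect_equal(clonal_variance(c(1, 1, 0, 2), c("A", "A", "B", "B")), 0.5)
  set.seed(20)
  for (i in 1:100) {
    n_clones <- sample(3:8, 1)
    clone <- sample(sprintf("cl%d", seq_len(n_clones)), 40, replace = TRUE)
    x <- rnorm(40)
    keep <- clone %in% names(which(table(clone) >= 2))
    expect_equal(clonal_variance(x, clone),
                 naive_clonal_variance(x[keep], clone[keep]))
  }
  expect_error(clonal_variance(c(1, 2), c("A", "B")), "at least")
})

test_that("Z, p and FDR obey their defining relations", {
  cfg <- sim_config(seed = 21, n_cells = 200, n_clones = 10,
                    n_features = 40, n_heritable = 10)
  sim <- simulate_clonal_scores(cfg)
  h <- clonal_heritability(sim$scores, sim$clone, n_perm = 200, seed = 21)
  res <- h$results
  ok <- !res$degenerate
  expect_equal(res$p[ok], 2 * stats::pnorm(-abs(res$Z[ok])))
  expect_true(all(res$fdr >= res$p - 1e-12))
  expect_true(all(res$p > 0 & res$p <= 1))
  # the documented Z example: obs 1, shuffled mean 2, sd 0.5 -> Z = -2
  expect_equal(2 * stats::pnorm(-abs((1 - 2) / 0.5)), 0.0455, tolerance = 1e-3)
  # S3 surface
  expect_output(print(h), "permutation")
  expect_s3_class(summary(h), "summary.clonal_heritability")
  expect_identical(as.data.frame(h), res)
})

test_that("a single clone is permutation-invariant and degenerate", {
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("f1", "f2")))
  h <- clonal_heritability(x, rep("only", 10), n_perm = 50)
  expect_true(all(h$results$degenerate))
  expect_true(all(h$results$p == 1))
})

test_that("sampled permutation null matches exhaustive enumeration", {
  set.seed(22)
  x <- rnorm(6)
  clone <- rep(c("A", "B"), each = 3)
  exact <- vapply(enumerate_assignments(clone), function(g)
    clonal_variance(x, g), numeric(1))
  expect_length(exact, 20)
  h <- clonal_heritability(x, clone, n_perm = 10000, seed = 23)
  expect_lt(abs(h$results$mean_shuffled - mean(exact)) / mean(exact), 0.02)
  sd_exact <- stats::sd(exact) * sqrt((length(exact) - 1) / length(exact))
  # permutations sample assignments i.i.d.; compare against the population SD
  expect_lt(abs(h$results$sd_shuffled - sd_exact) / sd_exact, 0.05)
})

test_that("permutation p-values are calibrated under the null", {
  cfg <- sim_config(seed = 24, n_cells = 600, n_clones = 30,
                    n_features = 150, n_heritable = 0, clone_sd = 0)
  sim <- simulate_clonal_scores(cfg)
  h <- clonal_heritability(sim$scores, sim$clone, n_perm = 400, seed = 24)
  expect_gt(stats::ks.test(h$results$p, "punif")$p.value, 0.01)
  expect_lt(mean(h$results$fdr < 0.05), 0.03)
})

test_that("planted clonal features are detected with high sensitivity", {
  cfg <- sim_config(seed = 25, n_cells = 1000, n_clones = 50,
                    n_features = 100, n_heritable = 20,
                    clone_sd = 1, noise_sd = 1)
  sim <- simulate_clonal_scores(cfg)
  h <- clonal_heritability(sim$scores, sim$clone, n_perm = 500, seed = 25)
  hits <- h$results$feature[h$results$fdr < 0.05]
  expect_gte(mean(sim$truth$heritable %in% hits), 0.9)
  # heritable features have less within-clone variance than shuffled
  expect_true(all(h$results$Z[h$results$feature %in% hits] < 0))
})

test_that("clone distribution comparison recovers planted differences", {
  x <- c(1, 1, 2, 2, 3, 3)
  cl <- c("a", "a", "b", "b", "c", "c")
  cc <- stats::setNames(rep("case", 3), c("a", "b", "c"))
  same <- compare_clone_distributions(c(x, x), c(cl, paste0(cl, "x")),
                                      c(cc, stats::setNames(rep("ctrl", 3),
                                                            paste0(names(cc), "x"))),
                                      case = "case", control = "ctrl")
  expect_equal(same$ks_p, 1)
  expect_equal(same$median_shift, 0)
  expect_equal(same$sd_shift, 0)

  # high-clone fraction: medians 1.3, 1.0, 2.0 -> 2/3; exactly 1.25 is not high
  sc <- c(1.3, 1.3, 1.0, 1.0, 2.0, 2.0, 1.25, 1.25)
  cl2 <- rep(c("a", "b", "c", "d"), each = 2)
  cc2 <- stats::setNames(rep("case", 4), c("a", "b", "c", "d"))
  out <- compare_clone_distributions(c(sc, sc), c(cl2, paste0(cl2, "x")),
                                     c(cc2, stats::setNames(rep("ctrl", 4),
                                                            paste0(names(cc2), "x"))),
                                     case = "case", control = "ctrl")
  expect_equal(unname(out$high_fraction["case"]), 0.5)  # 2 of 4 (1.25 excluded)

  cfg <- sim_config(seed = 26, n_cells = 2000, n_clones = 100,
                    n_features = 2, n_heritable = 2, clone_sd = 0.5,
                    noise_sd = 0.5,
                    conditions = c(control = 0, colitis = 0.4),
                    frac_high = 0.12, noise_ratio = 1.5)
  sim <- simulate_clonal_scores(cfg)
  cmp <- compare_clone_distributions(sim$scores[, 1], sim$clone,
                                     sim$truth$clone_condition,
                                     case = "colitis", control = "control")
  expect_lt(cmp$ks_p, 0.05)        # planted variance difference
  expect_gt(cmp$sd_shift, 0)
  expect_gt(cmp$high_fraction["colitis"], cmp$high_fraction["control"])
})

test_that("motif-program correlation is exact under affine coupling", {
  set.seed(27)
  n <- 200
  clone <- sample(sprintf("cl%02d", 1:20), n, replace = TRUE)
  m <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "AP1"))
  p <- 2 * m + 1
  colnames(p) <- "P20"
  out <- correlate_motifs_programs(m, p, clone)
  expect_equal(unname(out$cor["AP1", "P20"]), 1)
  expect_identical(unname(out$top_program["AP1"]), "P20")

  # null: independent clone means rarely correlate strongly at 50 clones
  clone2 <- rep(sprintf("cl%02d", 1:50), each = 4)
  m2 <- matrix(rnorm(200 * 5), 200, 5, dimnames = list(NULL, paste0("m", 1:5)))
  p2 <- matrix(rnorm(200 * 5), 200, 5, dimnames = list(NULL, paste0("p", 1:5)))
  out2 <- correlate_motifs_programs(m2, p2, clone2)
  expect_gt(mean(abs(out2$cor) < 0.4), 0.9)

  # zero-variance program -> NA
  p3 <- matrix(1, 200, 1, dimnames = list(NULL, "const"))
  out3 <- correlate_motifs_programs(m2, p3, clone2)
  expect_true(all(is.na(out3$cor)))
})
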