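test_that("bin exclusion drops bins that never reach the score floor", {
  fp <- data.frame(peak = rep("p1", 6), bin_start = rep(c(0, 10, 20), 2),
                   condition = rep(c("ctrl", "rec"), each = 3),
                   score = c(0.1, 0.25, 0.19, 0.15, 0.1, 0.21))
  out <- filter_footprint_bins(fp)
  expect_setequal(unique(out$bin_start), c(10, 20))  # max 0.15 < 0.2 at bin 0
})

test_that("quantile transform is the rank map on each condition", {
  x <- sort(stats::runif(11))
  fp <- data.frame(peak = "p", bin_start = seq(0, 100, 10),
                   condition = "a", score = x)
  out <- quantile_transform(fp)
  expect_equal(out$score, (0:10) / 10)
  # rank preservation and rank-equivalence across scales
  set.seed(60)
  y <- rnorm(50)
  fp2 <- rbind(data.frame(peak = "p", bin_start = 1:50, condition = "a",
                          score = y),
               data.frame(peak = "p", bin_start = 1:50, condition = "b",
                          score = 10 * y + 3))
  out2 <- quantile_transform(fp2)
  expect_equal(out2$score[out2$condition == "a"],
               out2$score[out2$condition == "b"])
  expect_equal(stats::cor(y, out2$score[out2$condition == "a"],
                          method = "kendall"), 1)
  expect_true(all(out2$score >= 0 & out2$score <= 1))
})

test_that("memory sites honour the inclusive 0.2 delta threshold", {
  fp <- data.frame(peak = rep("p1", 8),
                   bin_start = rep(c(0, 10, 20, 30), 2),
                   condition = rep(c("ctrl", "rec"), each = 4),
                   score = c(0.3, 0.3, 0.3, 0.3,
                             0.3, 0.50, 0.499, 0.51))
  sites <- data.frame(family = "AP1", peak = "p1",
                      bin_start = c(0, 10, 20, 30))
  mem <- call_memory_sites(fp, sites, case = "rec", control = "ctrl")
  expect_setequal(mem$AP1$bin_start, c(10, 30))   # delta 0.2 included, 0.199 not
  expect_equal(mem$AP1$midpoint, mem$AP1$bin_start + 5)
  # identical conditions: nothing called
  fp$score[fp$condition == "rec"] <- fp$score[fp$condition == "ctrl"]
  expect_identical(nrow(call_memory_sites(fp, sites, "rec", "ctrl")$AP1), 0L)
})

test_that("planted footprint gains are recovered exactly", {
  sf <- simulate_footprints(n_peaks = 200, seed = 61)
  mem <- call_memory_sites(sf$footprints, sf$sites, "recovered", "control")
  for (fam in names(mem)) {
    want <- sf$truth$memory_sites
    want <- want[want$family == fam, ]
    expect_setequal(paste(mem[[fam]]$peak, mem[[fam]]$bin_start),
                    paste(want$peak, want$bin_start))
  }
})

test_that("co-binding odds ratios match cross-product arithmetic", {
  mk <- function(peaks, bin) data.frame(peak = peaks, bin_start = bin,
                                        delta = 0.3, midpoint = bin + 5)
  universe <- sprintf("pk%03d", 1:100)
  mem <- structure(list(A = mk(universe[1:15], 0),
                        B = mk(universe[c(1:10, 16:20)], 10)),
                   class = c("memory_sites", "list"))
  cb <- cobinding_score(mem, universe)
  r <- cb[cb$family1 == "A" & cb$family2 == "B", ]
  expect_identical(c(r$both, r$first_only, r$second_only, r$neither),
                   c(10L, 5L, 5L, 80L))
  expect_equal(r$odds_ratio, 32)
  expect_equal(r$log2_or, 5)
  # symmetric pair agrees
  expect_equal(cb$log2_or[cb$family1 == "B"], 5)
  # single pair value: degenerate quantile range maps positives to 1
  expect_equal(r$score, 1)
})

test_that("empty memory sets yield missing co-binding entries", {
  universe <- sprintf("pk%03d", 1:50)
  mem <- structure(list(A = data.frame(peak = universe[1:5], bin_start = 0,
                                       delta = 0.3, midpoint = 5),
                        B = data.frame(peak = character(0),
                                       bin_start = numeric(0),
                                       delta = numeric(0),
                                       midpoint = numeric(0))),
                   class = c("memory_sites", "list"))
  cb <- cobinding_score(mem, universe)
  expect_true(all(is.na(cb$log2_or)))
})

test_that("co-binding scores stay in [-1, 1] and keep the sign", {
  set.seed(62)
  universe <- sprintf("pk%03d", 1:200)
  mem <- structure(lapply(stats::setNames(nm = c("A", "B", "C", "D")),
                          function(f)
                            data.frame(peak = sample(universe, 60),
                                       bin_start = 0, delta = 0.3,
                                       midpoint = 5)),
                   class = c("memory_sites", "list"))
  cb <- cobinding_score(mem, universe)
  expect_true(all(cb$score >= -1 & cb$score <= 1))
  expect_true(all(sign(cb$score) == sign(cb$log2_or) |
                    cb$score == 0 | abs(cb$log2_or) < 1e-9 |
                    (cb$score %in% c(-1, 0, 1))))
})

test_that("site distances pair only within shared peaks", {
  mem <- structure(list(
    A = data.frame(peak = c("p1", "p2"), bin_start = c(90, 0),
                   delta = 0.3, midpoint = c(100, 5)),
    B = data.frame(peak = c("p1", "p3"), bin_start = c(110, 0),
                   delta = 0.3, midpoint = c(115, 5))),
    class = c("memory_sites", "list"))
  expect_equal(site_distances(mem, "A", "B"), 15)
  mem$B$peak <- c("p4", "p3")
  expect_length(site_distances(mem, "A", "B"), 0)
})

test_that("planted site spacing shows up as the distance mode", {
  sf <- simulate_footprints(n_peaks = 300, pair_distance = 20, seed = 63)
  mem <- call_memory_sites(sf$footprints, sf$sites, "recovered", "control")
  d <- site_distances(mem, "AP1", "FOX")
  mode <- as.numeric(names(sort(-table(d)))[1])
  expect_lte(abs(mode - 20), 10)
})

test_that("overlapping sites collapse to the largest absolute change", {
  sites <- data.frame(peak = c("p1", "p1", "p1", "p2"),
                      start = c(0, 5, 30, 0), end = c(10, 15, 40, 10),
                      delta = c(0.1, -0.4, 0.2, 0.3))
  out <- collapse_overlapping_sites(sites)
  out <- out[order(out$peak, out$start), ]
  expect_identical(nrow(out), 3L)
  expect_equal(out$delta[out$peak == "p1" & out$start == 0], -0.4)
})

test_that("threshold sweep brackets perfect and null ranking", {
  perf <- footprint_binding_performance(c(4, 3.5, 3, 2.5, 1, 0.5, 0.2, 0),
                                        c(TRUE, TRUE, TRUE, TRUE,
                                          FALSE, FALSE, FALSE, FALSE))
  expect_true(any(perf$sensitivity == 1 & perf$specificity == 1))
  expect_equal(perf$sensitivity[1], 1)  # threshold below min
  expect_equal(perf$specificity[1], 0)
  set.seed(64)
  d <- rnorm(500); l <- sample(c(TRUE, FALSE), 500, replace = TRUE)
  perf2 <- footprint_binding_performance(d, l)
  auc <- -sum(diff(1 - perf2$specificity) *
                (utils::head(perf2$sensitivity, -1) +
                   utils::tail(perf2$sensitivity, -1)) / 2)
  expect_lt(abs(abs(auc) - 0.5), 0.1)
})
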