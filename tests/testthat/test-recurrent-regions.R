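# The multi-scale recurrent-region caller: aggregation arithmetic, the
# smoothing/extrema machinery against naive oracles, noise-free calls
# against exhaustive run enumeration, the nesting forest, and null
# calibration.

test_that("aggregate profile is the rectified per-bin sum", {
  m <- matrix(0, 3, 5)
  expect_equal(aggregate_profile(toy_binned(m), "gain")$values, rep(0, 5))

  m2 <- matrix(0, 3, 5); m2[, 3] <- 1.0
  expect_equal(aggregate_profile(toy_binned(m2), "gain")$values[3], 3.0)

  m3 <- matrix(0, 3, 4); m3[, 2] <- c(1, -1, 0.5)
  expect_equal(aggregate_profile(toy_binned(m3), "gain")$values[2], 1.5)
  expect_equal(aggregate_profile(toy_binned(m3), "loss")$values[2], 1.0)
})

test_that("box smoothing matches a naive window mean, per chromosome", {
  set.seed(31)
  for (i in 1:5) {
    x <- rnorm(60)
    for (h in c(0L, 1L, 3L, 10L)) {
      expect_equal(ampdriver:::box_smooth_cpp(x, 0L, 59L, h),
                   oracle_box_smooth(x, h), tolerance = 1e-12)
      # two chromosomes: smoothing must not cross the boundary
      expect_equal(ampdriver:::box_smooth_cpp(x, c(0L, 25L), c(24L, 59L), h),
                   c(oracle_box_smooth(x[1:25], h),
                     oracle_box_smooth(x[26:60], h)), tolerance = 1e-12)
    }
  }
})

test_that("extrema counting reproduces exhaustive run counts at any threshold", {
  set.seed(32)
  for (i in 1:20) {
    x <- round(rnorm(40), 1)  # rounding forces plateaus and ties
    ex <- ampdriver:::profile_extrema_cpp(x, 0L, 39L)
    for (t in c(sample(x, 5), -10, 10)) {
      runs_formula <- (length(ex$max) -
                         findInterval(t, ex$max, left.open = TRUE)) -
        (length(ex$min) - findInterval(t, ex$min, left.open = TRUE))
      expect_equal(runs_formula, nrow(oracle_runs(x, t)))
    }
  }
})

test_that("cyclic-shift null preserves the per-sample value multiset", {
  # with a single sample and one chromosome, every permuted aggregate is a
  # rotation of the rectified profile, so its maximum never changes
  set.seed(33)
  x <- pmax(rnorm(30), 0)
  b <- toy_binned(matrix(x, 1))
  ex <- ampdriver:::perm_null_extrema_cpp(
    t(b$matrix), 0L, 29L, 0L,
    matrix(sample.int(30, 200, replace = TRUE) - 1L, ncol = 1))
  # every permutation contributes the (rotated) global maximum
  expect_equal(sum(ex[[1]]$max == max(x)), 200)
  expect_true(all(ex[[1]]$max %in% x))
})

test_that("noise-free recurrent gains are called exactly, matching run enumeration", {
  n_samples <- 20
  m <- matrix(0, n_samples, 50)
  m[, 11:20] <- 1.0  # every sample gains bins 11..20
  b <- toy_binned(m)
  regs <- call_recurrent_regions(b, "gain", fdr_level = 0.01,
                                 scales = c(0, 2), n_permutations = 200,
                                 seed = 5)
  expect_gt(nrow(regs), 0)
  leaf <- regs[regs$is_leaf, ]
  expect_equal(nrow(leaf), 1)
  expect_equal(leaf$start, 10 * 100)  # bins 11..20 at 100 bp
  expect_equal(leaf$end, 20 * 100)
  expect_lte(leaf$q, 0.01)
  # every reported region is a maximal above-threshold run of the
  # independently smoothed aggregate (threshold = the region's lowest bin)
  A <- colSums(m)
  for (i in seq_len(nrow(regs))) {
    S <- oracle_box_smooth(A, regs$scale[i])
    bins_i <- (regs$start[i] / 100 + 1):(regs$end[i] / 100)
    oracle <- oracle_runs(S, min(S[bins_i]))
    j <- which(oracle$start == bins_i[1])
    expect_length(j, 1)
    expect_equal(oracle$end[j], bins_i[length(bins_i)])
    expect_equal(oracle$peak[j], regs$peak_stat[i])
  }
  # losses: none in this cohort
  expect_equal(nrow(call_recurrent_regions(b, "loss", 0.01, c(0, 2),
                                           200, seed = 5)), 0)
})

test_that("an all-zero cohort yields no regions, not an error", {
  b <- toy_binned(matrix(0, 4, 30))
  regs <- call_recurrent_regions(b, "gain", 0.01, c(0, 1), 200, seed = 1)
  expect_equal(nrow(regs), 0)
})

test_that("raising every gain amplitude never removes a called gain region", {
  m <- matrix(0, 15, 60)
  m[, 5:9] <- 0.8
  m[1:10, 40:44] <- 0.6
  for (mult in c(1, 1.5, 2.5)) {
    regs <- call_recurrent_regions(toy_binned(m * mult), "gain", 0.05,
                                   c(0, 1), 200, seed = 9)
    covered <- any(regs$start <= 400 & regs$end >= 900) &&
      any(regs$start <= 3900 & regs$end >= 4400)
    expect_true(covered)
  }
})

test_that("the nesting forest assigns parents, levels and leaves", {
  regs <- data.frame(chrom = "chr1", start = c(0, 4000), end = c(10000, 6000),
                     direction = "gain", scale = c(2, 0),
                     peak_stat = c(5, 9), q = 0.001,
                     stringsAsFactors = FALSE)
  nf <- nesting_forest(regs)
  expect_equal(nf$nesting_level, c(0, 1))
  expect_equal(nf$parent, c(NA_integer_, 1L))
  expect_equal(nf$is_leaf, c(FALSE, TRUE))

  three <- data.frame(chrom = "chr1", start = c(0, 10, 20),
                      end = c(100, 80, 40), direction = "gain",
                      scale = 0, peak_stat = 1, q = 0.01,
                      stringsAsFactors = FALSE)
  expect_equal(nesting_forest(three)$nesting_level, c(0, 1, 2))

  disjoint <- data.frame(chrom = "chr1", start = c(0, 50), end = c(40, 90),
                         direction = "gain", scale = 0, peak_stat = 1,
                         q = 0.01, stringsAsFactors = FALSE)
  nfd <- nesting_forest(disjoint)
  expect_equal(nfd$nesting_level, c(0, 0))
  expect_true(all(nfd$is_leaf))
})

test_that("pure-noise cohorts are almost never called at the configured FDR", {
  # under the global null the run-count estimator behaves like a
  # family-wise control: the chance of any call stays below the level
  called <- vapply(1:200, function(i) {
    set.seed(4000 + i)
    cohort <- toy_binned(matrix(rnorm(20 * 200, 0, 0.3), 20))
    regs <- call_recurrent_regions(cohort, "gain", fdr_level = 0.05,
                                   scales = c(0, 2, 8),
                                   n_permutations = 100, seed = 5000 + i)
    nrow(regs) > 0
  }, logical(1))
  rate <- mean(called)
  se <- sqrt(max(rate, 0.005) * (1 - max(rate, 0.005)) / 200)
  expect_lte(rate, 0.05 + 2 * se)
})

test_that("low permutation counts trigger a warning", {
  b <- toy_binned(matrix(1, 3, 20))
  expect_warning(call_recurrent_regions(b, "gain", 0.05, 0, 50, seed = 1),
                 "unstable")
})
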