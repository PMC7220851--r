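# Differential expression on knockdown counts: size factors, the NB Wald
# test, DEG calling, common DEGs and ddCT quantification.

test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(5, 10, 20, 5, 10, 20), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- cbind(a = c(5, 10, 20), b = c(10, 20, 40))
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  one <- matrix(c(4, 9), 1, dimnames = list("g1", c("a", "b")))
  expect_equal(unname(size_factors(one)), c(4 / 6, 9 / 6))

  set.seed(61)
  # odd gene count so the median ratio is a single element
  r <- matrix(rnbinom(606, mu = 50, size = 5), 101,
              dimnames = list(sprintf("g%03d", 1:101), NULL))
  expect_equal(unname(size_factors(r)), unname(oracle_size_factors(r)),
               tolerance = 1e-12)

  zeros <- matrix(c(0, 3, 4, 0), 2)
  expect_error(size_factors(zeros), "pseudo-reference")
})

test_that("size factors match the reference implementation", {
  set.seed(62)
  m <- matrix(rnbinom(2000, mu = 80, size = 8), 250)
  rownames(m) <- sprintf("g%03d", 1:250)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(size_factors(m)), unname(ref), tolerance = 1e-10)
})

test_that("the Wald test honors its definitions and filters", {
  cond <- rep(c("knockdown", "control"), each = 3)
  # identical groups: zero fold change, p near 1
  m <- matrix(rep(c(100, 40), each = 6), 2, 6, byrow = TRUE,
              dimnames = list(c("g1", "g2"), NULL))
  res <- nb_wald_test(m, cond, reference = "control", factors = rep(1, 6))
  expect_equal(res$log2FoldChange, c(0, 0))
  expect_equal(res$pvalue, c(1, 1))

  # 4x knockdown mean -> log2FC = 2
  m2 <- rbind(g1 = c(400, 400, 400, 100, 100, 100))
  r2 <- nb_wald_test(m2, cond, reference = "control", factors = rep(1, 6))
  expect_equal(r2$log2FoldChange, 2)

  # baseMean < 10 excluded; all-zero gene excluded
  m3 <- rbind(hi = rep(100, 6), lo = rep(2, 6), zero = rep(0, 6))
  r3 <- nb_wald_test(m3, cond, reference = "control", factors = rep(1, 6))
  expect_equal(r3$gene_id, "hi")

  expect_error(nb_wald_test(m3, rep("a", 6), reference = "a"),
               "two groups")
  expect_error(nb_wald_test(m3, c("a", "a", "a", "a", "a", "b"),
                            reference = "a"), ">= 2 samples")
})

test_that("DEG calling applies strict p and fold-change thresholds", {
  rec <- data.frame(gene_id = c("a", "b", "c", "d"),
                    baseMean = 100,
                    log2FoldChange = c(-1.5, 1.0, 3.0, 1.4),
                    stat = 0, pvalue = c(0.01, 0.01, 0.2, 0.04))
  d <- call_degs(rec, p_cut = 0.05, lfc_cut = 1)
  expect_equal(d$down, "a")
  expect_equal(d$up, "d")  # b is exactly at the cut, c fails on p
})

test_that("common DEGs follow the at-least-two-lines rule", {
  cd <- common_degs(list(c("a", "b"), c("b", "c"), "d"),
                    list(character(0), character(0), character(0)))
  expect_equal(cd$down, "b")
  expect_equal(cd$total, 1)

  all_same <- list(c("x", "y"), c("x", "y"), c("x", "y"))
  expect_equal(common_degs(all_same, all_same)$down, c("x", "y"))

  # disjoint direction sets of sizes 95 and 79 give a total of 174
  downs <- lapply(1:3, function(i) sprintf("d%03d", 1:95))
  ups <- lapply(1:3, function(i) sprintf("u%03d", 1:79))
  expect_equal(common_degs(downs, ups)$total, 174)
})

test_that("ddCT quantification is 2 to the minus delta-delta-CT", {
  expect_equal(ddct_quantify(20, 15, 20, 15), 1)    # ddCT = 0
  expect_equal(ddct_quantify(21, 15, 20, 15), 0.5)  # ddCT = 1
  expect_equal(ddct_quantify(18, 15, 20, 15), 4)    # ddCT = -2
})

test_that("null Wald p-values are approximately uniform", {
  cfg <- sim_config(seed = 5, counts = list(n_genes = 2000, dispersion = 0.1,
                                            deg_fraction = 0,
                                            knockdown_lfc = 0,
                                            n_replicates = 10))
  s <- simulate_counts(cfg)$CL1
  res <- nb_wald_test(s$counts, s$condition, reference = "control")
  ks <- suppressWarnings(ks.test(res$pvalue, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("the target gene's estimated knockdown matches the configured band", {
  # effect -1 (> 45% reduction); the estimate across cell lines and seeds
  # recovers it within the expected knockdown band
  est <- unlist(lapply(1:4, function(i) {
    cfg <- sim_config(seed = 70 + i, counts = list(n_genes = 400))
    sims <- simulate_counts(cfg)
    vapply(setdiff(names(sims), "truth"), function(li) {
      s <- sims[[li]]
      r <- nb_wald_test(s$counts, s$condition, reference = "control")
      r$log2FoldChange[r$gene_id == sims$truth$target_gene]
    }, numeric(1))
  }))
  expect_gt(mean(est), -1.5)
  expect_lt(mean(est), -0.7)
})

test_that("affected genes' mean estimated log2FC recovers the simulated effect", {
  cfg <- sim_config(seed = 9, counts = list(n_genes = 500,
                                            deg_fraction = 0.3,
                                            deg_lfc_range = c(1, 1),
                                            deg_carry_prob = 1))
  s <- simulate_counts(cfg)
  eff <- s$truth$deg_effects[, "CL1"]
  r <- nb_wald_test(s$CL1$counts, s$CL1$condition, reference = "control")
  down <- names(eff)[eff == -1]
  m <- mean(r$log2FoldChange[r$gene_id %in% down])
  expect_gt(m, -1.25)
  expect_lt(m, -0.75)
})
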