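# Focal-region filtering, Spearman correlation, BH adjustment, candidate
# selection and cohort merging.

test_that("focal filter keeps leaf gain regions spanning 1-100 genes", {
  genes <- toy_genes("chr1", seq(0, 100 * 1000 - 1, by = 1000), width = 500)
  ann <- toy_annotation(c(chr1 = 2e5), genes)  # 100 genes in [0, 1e5)
  mk <- function(start, end, leaf) {
    data.frame(chrom = "chr1", start = start, end = end,
               direction = "gain", scale = 0, peak_stat = 1, q = 0.001,
               nesting_level = 1, parent = NA, is_leaf = leaf,
               stringsAsFactors = FALSE)
  }
  expect_equal(nrow(filter_focal_regions(mk(0, 1e5, TRUE), ann)), 1)
  # widen to catch one more gene -> 101 genes -> dropped
  extra <- toy_annotation(c(chr1 = 2e5),
                          rbind(genes, toy_genes("chr1", 100500,
                                                 ids = "g101")))
  expect_equal(nrow(filter_focal_regions(mk(0, 1.02e5, TRUE), extra)), 0)
  # non-leaf regions are dropped regardless of gene count
  expect_equal(nrow(filter_focal_regions(mk(0, 5000, FALSE), ann)), 0)
  # zero genes -> below min_genes
  expect_equal(nrow(filter_focal_regions(mk(1.5e5, 1.6e5, TRUE), ann)), 0)
})

test_that("Spearman correlation handles monotone, anti-monotone and tied inputs", {
  expect_equal(spearman_cn_expression(1:4, c(2, 4, 6, 8))$rho, 1)
  expect_equal(spearman_cn_expression(1:4, c(8, 6, 4, 2))$rho, -1)
  r <- spearman_cn_expression(1:5, c(1, 3, 2, 5, 4))
  expect_equal(r$rho, 0.8)  # sum of squared rank differences is 4
  expect_equal(r$rho, oracle_spearman(1:5, c(1, 3, 2, 5, 4)))

  set.seed(51)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- sample(round(rnorm(n), 1))  # duplicates force average ranks
    y <- round(rnorm(n), 1)
    got <- spearman_cn_expression(x, y)
    expect_equal(got$rho, oracle_spearman(x, y), tolerance = 1e-12)
    expect_equal(got$rho, suppressWarnings(cor(x, y, method = "spearman")),
                 tolerance = 1e-12)
    # p via the t approximation
    tstat <- got$rho * sqrt((n - 2) / (1 - got$rho^2))
    expect_equal(got$p, 2 * pt(-abs(tstat), n - 2), tolerance = 1e-12)
  }

  expect_warning(out <- spearman_cn_expression(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out$rho))
  expect_error(spearman_cn_expression(1:3, 1:3), "at least 4")
  expect_error(spearman_cn_expression(1:5, 1:4), "unequal")
})

test_that("BH adjustment agrees with the step-up definition", {
  got <- bh_adjust(c(0.001, 0.02, 0.03, 0.9), 0.1)
  expect_equal(got$reject, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(bh_adjust(rep(1, 6), 0.1)$reject, rep(FALSE, 6))
  expect_true(bh_adjust(0.05, 0.1)$reject)  # m = 1

  set.seed(52)
  for (i in 1:30) {
    m <- sample(1:10, 1)
    p <- round(runif(m), 3)
    p[p == 0] <- 1e-4
    alpha <- sample(c(0.05, 0.1, 0.2), 1)
    expect_equal(bh_adjust(p, alpha)$reject, oracle_bh_reject(p, alpha))
  }
  expect_error(bh_adjust(c(0.5, 0), 0.1), "0, 1")
})

test_that("the correlation filter retains true couplings and respects its FDR", {
  # strong couplings, small cohort: all coupled genes kept, FDP small on
  # average
  fdps <- vapply(1:20, function(i) {
    cc <- simulate_coupling_cohort(seed = 600 + i, n_genes = 100,
                                   n_samples = 100, frac_coupled = 0.05)
    tab <- cn_expression_candidates(rownames(cc$cn), cc$cn, cc$expression,
                                    fdr_level = 0.1)
    sel <- tab$gene_id[tab$selected]
    expect_true(all(cc$coupled %in% sel))
    if (!length(sel)) 0 else mean(!(sel %in% cc$coupled))
  }, numeric(1))
  expect_lte(mean(fdps), 0.1 + 2 * sd(fdps) / sqrt(length(fdps)))

  # no coupling anywhere: nearly nothing retained
  n_sel <- vapply(1:10, function(i) {
    cc <- simulate_coupling_cohort(seed = 700 + i, n_genes = 100,
                                   n_samples = 50, frac_coupled = 0)
    sum(cn_expression_candidates(rownames(cc$cn), cc$cn, cc$expression,
                                 0.1)$selected)
  }, numeric(1))
  expect_lte(mean(n_sel), 0.5)

  # a perfect noise-free coupling is retained with rho exactly 1
  cn <- matrix(seq_len(10), 1, dimnames = list("g1", paste0("S", 1:10)))
  tab <- cn_expression_candidates("g1", cn, cn * 2 + 1, 0.1)
  expect_equal(tab$spearman_rho, 1)
  expect_true(tab$selected)
})

test_that("selected candidates always have positive rho", {
  for (i in 1:5) {
    cc <- simulate_coupling_cohort(seed = 800 + i, n_genes = 60,
                                   n_samples = 30, frac_coupled = 0.2)
    tab <- cn_expression_candidates(rownames(cc$cn), cc$cn, cc$expression,
                                    0.2)
    expect_true(all(tab$spearman_rho[tab$selected] > 0))
  }
})

test_that("cohort merging is a provenance-keeping union (or intersection)", {
  la <- data.frame(gene_id = c("a", "b"), cohort = "A")
  lb <- data.frame(gene_id = c("b", "c"), cohort = "B")
  m <- merge_cohort_candidates(la, lb)
  expect_equal(m$gene_id, c("a", "b", "c"))
  expect_equal(m$cohorts, c("A", "A,B", "B"))
  expect_equal(merge_cohort_candidates(la, la)$gene_id, c("a", "b"))
  ld <- data.frame(gene_id = c("x", "y", "z", "w"), cohort = "D")
  lc <- data.frame(gene_id = c("p", "q", "r"), cohort = "C")
  expect_equal(nrow(merge_cohort_candidates(lc, ld)), 7)
  expect_equal(merge_cohort_candidates(la, lb,
                                       mode = "intersection")$gene_id, "b")
})
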