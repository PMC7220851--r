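# Generators: determinism, exact degenerate behavior, and marginal
# statistics against their configured values.

test_that("all generators are pure functions of the configuration", {
  cfg <- sim_config(seed = 11, n_samples = 8, n_bins = 80, n_genes = 40,
                    screen = list(n_genes = 30),
                    counts = list(n_genes = 60))
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  expect_identical(simulate_screen(cfg), simulate_screen(cfg))
  expect_identical(simulate_counts(cfg), simulate_counts(cfg))
  expect_identical(simulate_survival(cfg), simulate_survival(cfg))
  expect_identical(simulate_coupling_cohort(3, n_genes = 50, n_samples = 20),
                   simulate_coupling_cohort(3, n_genes = 50, n_samples = 20))
})

test_that("full-penetrance noise-free gains produce exactly the amplitude", {
  loci <- data.frame(chrom = "chr1", start = 2e5, end = 6e5,
                     penetrance = 1, amplitude = 1.0)
  cfg <- sim_config(seed = 2, n_samples = 12, n_chromosomes = 2,
                    n_bins = 40, n_genes = 10, driver_loci = loci,
                    segment_noise_sd = 0)
  sim <- simulate_cohort(cfg)
  b <- segments_to_bins(sim$cohort, sim$annotation, cfg$bin_size)
  driver_bins <- b$bins$chrom == "chr1" & b$bins$start >= 2e5 &
    b$bins$end <= 6e5
  expect_true(all(b$matrix[, driver_bins] == 1.0))
  expect_true(all(b$matrix[, !driver_bins] == 0))
})

test_that("observed gain frequency matches the configured penetrance", {
  loci <- data.frame(chrom = "chr1", start = 1e5, end = 3e5,
                     penetrance = 0.5, amplitude = 1.0)
  cfg <- sim_config(seed = 8, n_samples = 400, n_chromosomes = 2,
                    n_bins = 40, n_genes = 10, driver_loci = loci,
                    segment_noise_sd = 0)
  sim <- simulate_cohort(cfg)
  freq <- mean(sim$truth$carried[1, ])
  se <- sqrt(0.5 * 0.5 / 400)
  expect_lt(abs(freq - 0.5), 3 * se)
})

test_that("overlapping driver loci are a configuration error", {
  loci <- data.frame(chrom = "chr1", start = c(0, 1e5), end = c(2e5, 3e5),
                     penetrance = 0.5, amplitude = 1)
  expect_error(sim_config(driver_loci = loci), "overlap")
})

test_that("every simulated driver gene lies inside a driver locus", {
  cfg <- sim_config(seed = 21, n_samples = 5, n_bins = 200, n_genes = 100)
  sim <- simulate_cohort(cfg)
  g <- sim$annotation$genes
  loci <- sim$truth$driver_loci
  for (gid in sim$truth$driver_genes) {
    gi <- g[g$gene_id == gid, ]
    expect_true(any(loci$chrom == gi$chrom & loci$start < gi$end &
                    loci$end > gi$start))
  }
})

test_that("noise-free screens normalize to exactly 100*(1-effect)", {
  cfg0 <- sim_config(seed = 4, screen = list(n_genes = 20,
                                             replicate_noise_sd = 0,
                                             driver_fraction = 0))
  scr <- simulate_screen(cfg0, gene_ids = paste0("g", 1:20),
                         effects = rep(0, 20))
  pct <- normalize_proliferation(scr$plates)
  expect_true(all(pct$percent_proliferation == 100))

  scr2 <- simulate_screen(cfg0, gene_ids = paste0("g", 1:20),
                          effects = rep(0.5, 20))
  pct2 <- normalize_proliferation(scr2$plates)
  expect_true(all(pct2$percent_proliferation[!pct2$is_control] == 50))
})

test_that("duplicate screens are highly concordant at the default noise", {
  cfg <- sim_config(seed = 13, screen = list(n_genes = 300,
                                             replicate_noise_sd = 0.02))
  scr <- simulate_screen(cfg)
  p <- scr$plates
  g1 <- p[p$cell_line == "LINE1" & !p$is_control & p$replicate == 1, ]
  g2 <- p[p$cell_line == "LINE1" & !p$is_control & p$replicate == 2, ]
  expect_gt(replicate_concordance(g1$raw[order(g1$gene_id)],
                                  g2$raw[order(g2$gene_id)]), 0.95)
})

test_that("NB counts track their configured moments and effects", {
  # near-Poisson limit with no effects: knockdown/control mean ratios -> 1
  cfg <- sim_config(seed = 6, counts = list(n_genes = 300,
                                            dispersion = 1e-6,
                                            deg_fraction = 0,
                                            knockdown_lfc = 0,
                                            n_replicates = 20,
                                            size_factor_range = c(1, 1)))
  s <- simulate_counts(cfg)$CL1
  kd <- rowMeans(s$counts[, s$condition == "knockdown"])
  ct <- rowMeans(s$counts[, s$condition == "control"])
  ok <- ct > 50
  expect_lt(median(abs(log2(kd[ok] / ct[ok]))), 0.05)

  # mean/variance relation: var ~ mu + alpha mu^2 at alpha = 0.2
  cfg2 <- sim_config(seed = 7, counts = list(n_genes = 2000,
                                             dispersion = 0.2,
                                             deg_fraction = 0,
                                             knockdown_lfc = 0,
                                             n_replicates = 25,
                                             size_factor_range = c(1, 1)))
  s2 <- simulate_counts(cfg2)$CL1
  mu <- rowMeans(s2$counts)
  v <- apply(s2$counts, 1, var)
  big <- mu > 200
  alpha_hat <- median((v[big] - mu[big]) / mu[big]^2)
  expect_lt(abs(alpha_hat - 0.2), 0.05)
})

test_that("a knockdown effect of -1 is recovered by the estimator", {
  cfg <- sim_config(seed = 9, counts = list(n_genes = 500,
                                            knockdown_lfc = -1,
                                            deg_fraction = 0,
                                            n_replicates = 25,
                                            dispersion = 0.05))
  s <- simulate_counts(cfg)$CL1
  res <- nb_wald_test(s$counts, s$condition, reference = "control")
  expect_lt(abs(res$log2FoldChange[res$gene_id == "CG0001"] - (-1)), 0.2)
})

test_that("survival generator honors its censoring rate and hazard direction", {
  cfg1 <- sim_config(seed = 10, survival = list(censoring_rate = 1))
  expect_true(all(simulate_survival(cfg1)$event == 0))
  cfg0 <- sim_config(seed = 10, survival = list(censoring_rate = 0))
  expect_true(all(simulate_survival(cfg0)$event == 1))

  # gamma = 0: censored fraction matches the configured rate exactly in
  # expectation
  cfgc <- sim_config(seed = 12, survival = list(censoring_rate = 0.3,
                                                gamma = 0,
                                                n_patients = 2000))
  sv <- simulate_survival(cfgc)
  expect_lt(abs(mean(sv$event == 0) - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))

  # gamma > 0: the high-score arm sits below the low-score arm at median
  # follow-up in nearly all replicates
  worse <- vapply(1:100, function(i) {
    cfg <- sim_config(seed = 100 + i,
                      survival = list(gamma = 1, n_patients = 200))
    sv <- simulate_survival(cfg)
    hi <- sv$score > median(sv$score)
    tmid <- median(sv$time)
    s_at <- function(g) {
      km <- km_curve(sv$time[g], sv$event[g])
      km$surv[findInterval(tmid, km$time)]
    }
    s_at(hi) < s_at(!hi)
  }, logical(1))
  expect_gte(mean(worse), 0.95)
})
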