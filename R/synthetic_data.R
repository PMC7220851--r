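# Synthetic-data generators. They emulate the statistical structure the
# analysis assumes -- segmented tumor copy-number profiles with recurrent
# focal gains, expression coupled to copy number at driver genes, duplicate
# proliferation screens, negative-binomial knockdown counts, and survival
# times with expression-dependent hazard -- so that every downstream stage
# is testable without external downloads. All randomness flows from the
# single seed in the configuration through named substreams, so each
# generator is independently reproducible.

# Deterministic per-component substream seeds spawned from the root seed.
substream_seed <- function(seed, stream) {
  streams <- c("cohort", "expression", "screen", "counts", "survival",
               "coupling", "pipeline", "aux")
  i <- match(stream, streams)
  if (is.na(i)) stop("unknown substream: ", stream)
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, length(streams))[i]
}

#' Simulation configuration
#'
#' One configuration object drives every generator. Defaults describe a
#' desk-scale tumor cohort: 100 samples, 2,000 bins of 100 kb on 4
#' chromosomes, 1,000 genes, and three focal gain loci carried with
#' penetrance 0.6 at +1 log2 unit over segment-level Gaussian noise
#' (sd 0.3); driver-gene expression follows copy number with unit slope and
#' residual sd 0.5.
#'
#' @param seed root integer seed; all generators derive substreams from it.
#' @param n_samples samples per cohort.
#' @param n_chromosomes,n_bins,bin_size genome shape: `n_bins` total bins of
#'   `bin_size` bp split evenly over `n_chromosomes` chromosomes.
#' @param driver_loci data.frame (`chrom`, `start`, `end`, `penetrance`,
#'   `amplitude`) of focal gain loci, or `NULL` for the default of three
#'   loci (4% of a chromosome wide) on the first three chromosomes.
#' @param segment_noise_sd sd of the per-segment background log2 ratio.
#'   Noise is drawn per segment, not per bin, to mimic segmented input.
#' @param mean_segment_bins mean background segment length, in bins.
#' @param n_genes,gene_length genes evenly spaced along the genome.
#' @param cn_expression_slope log2-expression units gained per log2
#'   copy-number unit at driver genes (passengers have slope 0).
#' @param expression_noise_sd residual sd of log2 expression.
#' @param expression_baseline mean baseline log2 expression.
#' @param screen list: `n_genes`, `n_cell_lines`, `n_replicates`,
#'   `n_controls` control wells per plate, `control_level` raw absorbance of
#'   an untreated well, `replicate_noise_sd` multiplicative readout noise,
#'   `driver_fraction` of genes with a real proliferation effect,
#'   `driver_effect_range` / `passenger_effect_range` uniform ranges for the
#'   fractional inhibition effect (in \[0,1\]), `deconv_noise_sd` sd of the
#'   per-single-siRNA effect perturbation, `n_tnbc_lines` cell lines in the
#'   copy-number status panel.
#' @param counts list: `n_genes`, `n_cell_lines`, `n_replicates` per group,
#'   `dispersion` NB dispersion, `knockdown_lfc` log2 effect on the
#'   knocked-down target gene itself, `deg_fraction` of genes truly
#'   responding, `deg_lfc_range` magnitude range of their log2 effects,
#'   `deg_carry_prob` probability a designated responder is active in a
#'   given cell line, `mean_log2_mu`, `sd_log2_mu` log2-normal gene mean
#'   parameters, `size_factor_range` uniform range of true size factors.
#' @param survival list: `n_patients`, `baseline_hazard` (events per month),
#'   `gamma` log-hazard slope per score unit, `censoring_rate` expected
#'   censored fraction in \[0,1\].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_samples = 100,
                       n_chromosomes = 4,
                       n_bins = 2000,
                       bin_size = 1e5,
                       driver_loci = NULL,
                       segment_noise_sd = 0.3,
                       mean_segment_bins = 20,
                       n_genes = 1000,
                       gene_length = 3e4,
                       cn_expression_slope = 1.0,
                       expression_noise_sd = 0.5,
                       expression_baseline = 7,
                       screen = list(),
                       counts = list(),
                       survival = list()) {
  screen_def <- list(n_genes = 138, n_cell_lines = 2, n_replicates = 2,
                     n_controls = 8, control_level = 1.0,
                     replicate_noise_sd = 0.02, driver_fraction = 0.15,
                     driver_effect_range = c(0.45, 0.8),
                     passenger_effect_range = c(0, 0.2),
                     deconv_noise_sd = 0.1, n_tnbc_lines = 20)
  counts_def <- list(n_genes = 2000, n_cell_lines = 3, n_replicates = 3,
                     dispersion = 0.1, knockdown_lfc = -1,
                     deg_fraction = 0.075, deg_lfc_range = c(1, 2),
                     deg_carry_prob = 0.8, mean_log2_mu = 6,
                     sd_log2_mu = 2.5, size_factor_range = c(0.7, 1.3))
  survival_def <- list(n_patients = 300, baseline_hazard = 0.02,
                       gamma = log(2), censoring_rate = 0.3)
  merge_block <- function(def, user, what) {
    if (length(user) && !all(names(user) %in% names(def)))
      stop("unknown ", what, " option(s): ",
           paste(setdiff(names(user), names(def)), collapse = ", "))
    def[names(user)] <- user
    def
  }
  cfg <- list(seed = as.integer(seed), n_samples = n_samples,
              n_chromosomes = n_chromosomes, n_bins = n_bins,
              bin_size = bin_size, driver_loci = driver_loci,
              segment_noise_sd = segment_noise_sd,
              mean_segment_bins = mean_segment_bins, n_genes = n_genes,
              gene_length = gene_length,
              cn_expression_slope = cn_expression_slope,
              expression_noise_sd = expression_noise_sd,
              expression_baseline = expression_baseline,
              screen = merge_block(screen_def, screen, "screen"),
              counts = merge_block(counts_def, counts, "counts"),
              survival = merge_block(survival_def, survival, "survival"))
  if (is.null(cfg$driver_loci)) {
    bins_per_chrom <- cfg$n_bins %/% cfg$n_chromosomes
    width <- max(1, round(bins_per_chrom * 0.04)) * cfg$bin_size
    k <- min(3, cfg$n_chromosomes)
    starts <- floor(bins_per_chrom * seq_len(k) / 4) * cfg$bin_size
    cfg$driver_loci <- data.frame(
      chrom = paste0("chr", seq_len(k)), start = starts,
      end = starts + width, penetrance = 0.6, amplitude = 1.0,
      stringsAsFactors = FALSE)
  }
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  loci <- cfg$driver_loci
  stopifnot(is.data.frame(loci),
            all(c("chrom", "start", "end", "penetrance", "amplitude") %in%
                names(loci)))
  if (any(loci$penetrance <= 0 | loci$penetrance > 1))
    stop("gain penetrance must lie in (0, 1]")
  if (any(loci$end <= loci$start)) stop("driver locus with end <= start")
  # loci must not overlap each other
  if (nrow(loci) > 1) {
    o <- order(loci$chrom, loci$start)
    l <- loci[o, ]
    same <- l$chrom[-1] == l$chrom[-nrow(l)]
    if (any(same & l$start[-1] < l$end[-nrow(l)]))
      stop("driver loci overlap each other")
  }
  if (cfg$segment_noise_sd < 0 || cfg$expression_noise_sd < 0 ||
      cfg$screen$replicate_noise_sd < 0)
    stop("noise sds must be >= 0")
  if (cfg$counts$dispersion <= 0) stop("NB dispersion must be > 0")
  if (cfg$survival$censoring_rate < 0 || cfg$survival$censoring_rate > 1)
    stop("censoring rate must lie in [0, 1]")
  eff <- c(cfg$screen$driver_effect_range, cfg$screen$passenger_effect_range)
  if (any(eff < 0 | eff > 1)) stop("screen effects must lie in [0, 1]")
  invisible(cfg)
}

# Genome + evenly spaced genes implied by a sim_config (deterministic).
sim_annotation <- function(cfg) {
  bins_per_chrom <- cfg$n_bins %/% cfg$n_chromosomes
  chroms <- data.frame(chrom = paste0("chr", seq_len(cfg$n_chromosomes)),
                       length = bins_per_chrom * cfg$bin_size,
                       stringsAsFactors = FALSE)
  total <- sum(chroms$length)
  spacing <- total / cfg$n_genes
  glen <- min(cfg$gene_length, floor(0.6 * spacing))
  gstart <- floor((seq_len(cfg$n_genes) - 1) * spacing + 0.2 * spacing)
  cum <- c(0, cumsum(chroms$length))
  ci <- findInterval(gstart, cum, left.open = FALSE)
  ci[ci > nrow(chroms)] <- nrow(chroms)
  genes <- data.frame(gene_id = sprintf("G%04d", seq_len(cfg$n_genes)),
                      chrom = chroms$chrom[ci],
                      start = gstart - cum[ci],
                      end = pmin(gstart - cum[ci] + glen, chroms$length[ci]),
                      strand = rep(c("+", "-"), length.out = cfg$n_genes),
                      stringsAsFactors = FALSE)
  genome_annotation(chroms, genes)
}

# Replace [start, end) of a sorted segment list with a single segment.
overwrite_interval <- function(seg, start, end, value) {
  keep_l <- seg[seg$start < start, , drop = FALSE]
  keep_l$end <- pmin(keep_l$end, start)
  keep_r <- seg[seg$end > end, , drop = FALSE]
  keep_r$start <- pmax(keep_r$start, end)
  out <- rbind(keep_l,
               data.frame(start = start, end = end, log2_ratio = value),
               keep_r)
  out <- out[out$end > out$start, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Simulate a tumor cohort with recurrent focal gains and coupled expression
#'
#' Each sample's genome is partitioned into background segments (geometric
#' lengths, mean `mean_segment_bins` bins) with segment-level Gaussian log2
#' noise; each driver locus is then carried with its configured penetrance,
#' overwriting the locus interval with the gain amplitude. Driver-gene
#' expression is `baseline + slope * gene-level CN + noise`; passenger genes
#' have slope 0. Truth labels record the loci, the genes inside them, and
#' the per-sample carrier status.
#'
#' @param config a [sim_config()].
#' @return list with `annotation`, `cohort` (segmented profiles),
#'   `expression` (genes x samples log2 matrix), and `truth` (list:
#'   `driver_loci`, `driver_genes`, `carried` loci x samples logical
#'   matrix).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  ann <- sim_annotation(config)
  loci <- config$driver_loci
  set.seed(substream_seed(config$seed, "cohort"))
  sample_ids <- sprintf("S%03d", seq_len(config$n_samples))
  carried <- matrix(FALSE, nrow = nrow(loci), ncol = config$n_samples,
                    dimnames = list(NULL, sample_ids))
  segs <- vector("list", config$n_samples)
  for (s in seq_len(config$n_samples)) {
    per_chrom <- vector("list", nrow(ann$chromosomes))
    for (ci in seq_len(nrow(ann$chromosomes))) {
      clen <- ann$chromosomes$length[ci]
      nb <- clen / config$bin_size
      # geometric background segment lengths, in bins, until coverage
      lens <- integer(0)
      while (sum(lens) < nb)
        lens <- c(lens, rgeom(8, 1 / config$mean_segment_bins) + 1L)
      bounds <- pmin(cumsum(lens), nb) * config$bin_size
      bounds <- unique(bounds)
      starts <- c(0, bounds[-length(bounds)])
      vals <- if (config$segment_noise_sd > 0)
        rnorm(length(starts), 0, config$segment_noise_sd) else
        numeric(length(starts))
      seg <- data.frame(start = starts, end = bounds, log2_ratio = vals)
      for (li in which(loci$chrom == ann$chromosomes$chrom[ci])) {
        carry <- runif(1) < loci$penetrance[li]
        carried[li, s] <- carry
        if (carry)
          seg <- overwrite_interval(seg, loci$start[li], loci$end[li],
                                    loci$amplitude[li])
      }
      seg$chrom <- ann$chromosomes$chrom[ci]
      per_chrom[[ci]] <- seg
    }
    sc <- do.call(rbind, per_chrom)
    sc$sample <- sample_ids[s]
    segs[[s]] <- sc
  }
  cohort <- do.call(rbind, segs)[, c("sample", "chrom", "start", "end",
                                     "log2_ratio")]
  rownames(cohort) <- NULL

  g <- ann$genes
  in_locus <- vapply(seq_len(nrow(g)), function(i) {
    any(loci$chrom == g$chrom[i] & loci$start < g$end[i] &
        loci$end > g$start[i])
  }, logical(1))
  driver_genes <- g$gene_id[in_locus]

  cn <- gene_level_cn(cohort, ann)
  set.seed(substream_seed(config$seed, "expression"))
  baseline <- rnorm(nrow(g), config$expression_baseline, 1)
  slope <- ifelse(in_locus, config$cn_expression_slope, 0)
  noise <- matrix(rnorm(length(cn), 0, config$expression_noise_sd),
                  nrow = nrow(cn))
  expr <- baseline + slope * cn + noise
  dimnames(expr) <- dimnames(cn)

  list(annotation = ann, cohort = cohort, expression = expr,
       truth = list(driver_loci = loci, driver_genes = driver_genes,
                    carried = carried))
}

#' Simulate duplicate siRNA proliferation screens
#'
#' Raw readout for a gene well is
#' `control_level * (1 - effect) * (1 + noise)`; control wells omit the
#' effect term. Two replicates per cell line by default, plus a
#' single-replicate deconvolution table (SMARTpool and the 4 single siRNAs,
#' with per-single effects jittered around the pool effect) and a synthetic
#' copy-number status panel over `n_tnbc_lines` cell lines in which true
#' proliferation drivers gain far more often than passengers.
#'
#' @param config a [sim_config()].
#' @param gene_ids optional gene identifiers for the screened set (defaults
#'   to `SG001`, ...).
#' @param effects optional per-gene fractional inhibition effects in
#'   \[0, 1\]; defaults are drawn from the configured driver/passenger
#'   ranges.
#' @return list with `plates` (long data.frame: `cell_line`, `replicate`,
#'   `well`, `gene_id`, `raw`, `is_control`), `deconv` (`cell_line`,
#'   `gene_id`, `sirna` in pool/s1..s4/ctrl, `raw`, `is_control`),
#'   `cna_status` (genes x cell-line panel, values `++`, `+`, `/`, `-`),
#'   and `truth` (`effects`, `drivers`).
#' @export
simulate_screen <- function(config, gene_ids = NULL, effects = NULL) {
  validate_sim_config(config)
  sc <- config$screen
  set.seed(substream_seed(config$seed, "screen"))
  if (is.null(gene_ids))
    gene_ids <- sprintf("SG%03d", seq_len(sc$n_genes))
  n <- length(gene_ids)
  if (is.null(effects)) {
    n_drv <- round(sc$driver_fraction * n)
    drivers <- sort(sample.int(n, n_drv))
    effects <- runif(n, sc$passenger_effect_range[1],
                     sc$passenger_effect_range[2])
    effects[drivers] <- runif(n_drv, sc$driver_effect_range[1],
                              sc$driver_effect_range[2])
  } else {
    if (length(effects) != n) stop("effects must match gene_ids")
    drivers <- which(effects > 0.4)
  }
  if (any(effects < 0 | effects > 1))
    stop("screen effects must lie in [0, 1]")

  lines <- paste0("LINE", seq_len(sc$n_cell_lines))
  noise <- function(k) if (sc$replicate_noise_sd > 0)
    rnorm(k, 0, sc$replicate_noise_sd) else numeric(k)
  plates <- list()
  for (cl in lines) {
    for (rep_i in seq_len(sc$n_replicates)) {
      raw_g <- sc$control_level * (1 - effects) * (1 + noise(n))
      raw_c <- sc$control_level * (1 + noise(sc$n_controls))
      plates[[length(plates) + 1L]] <- data.frame(
        cell_line = cl, replicate = rep_i,
        well = c(gene_ids, sprintf("CTRL%02d", seq_len(sc$n_controls))),
        gene_id = c(gene_ids, rep(NA_character_, sc$n_controls)),
        raw = c(raw_g, raw_c),
        is_control = rep(c(FALSE, TRUE), c(n, sc$n_controls)),
        stringsAsFactors = FALSE)
    }
  }
  plates <- do.call(rbind, plates)

  # deconvolution: 3 validation lines, pool + 4 singles, one replicate
  dlines <- paste0("LINE", seq_len(max(3, sc$n_cell_lines)))
  deconv <- list()
  for (cl in dlines) {
    single_eff <- pmin(pmax(rep(effects, each = 4) +
                            rnorm(4 * n, 0, sc$deconv_noise_sd), 0), 1)
    raw <- sc$control_level *
      (1 - c(rbind(effects, matrix(single_eff, nrow = 4)))) *
      (1 + noise(5 * n))
    deconv[[length(deconv) + 1L]] <- data.frame(
      cell_line = cl,
      gene_id = c(rep(gene_ids, each = 5), rep(NA_character_, sc$n_controls)),
      sirna = c(rep(c("pool", "s1", "s2", "s3", "s4"), n),
                rep("ctrl", sc$n_controls)),
      raw = c(raw, sc$control_level * (1 + noise(sc$n_controls))),
      is_control = rep(c(FALSE, TRUE), c(5 * n, sc$n_controls)),
      stringsAsFactors = FALSE)
  }
  deconv <- do.call(rbind, deconv)

  # synthetic CNA status panel: drivers gain in most lines
  p_gain <- ifelse(seq_len(n) %in% drivers, 0.6, 0.15)
  gain <- matrix(runif(n * sc$n_tnbc_lines) <
                 rep(p_gain, sc$n_tnbc_lines), nrow = n)
  high <- gain & matrix(runif(n * sc$n_tnbc_lines) < 0.3, nrow = n)
  loss <- !gain & matrix(runif(n * sc$n_tnbc_lines) < 0.05, nrow = n)
  status <- matrix("/", nrow = n, ncol = sc$n_tnbc_lines,
                   dimnames = list(gene_ids,
                                   paste0("TNBC", seq_len(sc$n_tnbc_lines))))
  status[gain] <- "+"
  status[high] <- "++"
  status[loss] <- "-"

  list(plates = plates, deconv = deconv, cna_status = status,
       truth = list(gene_ids = gene_ids, effects = effects,
                    drivers = gene_ids[drivers]))
}

#' Simulate knockdown count matrices across cell lines
#'
#' Negative-binomial counts for `n_genes` genes in `n_replicates` knockdown
#' plus `n_replicates` control samples per cell line. A designated responder
#' set is shifted by gene-specific log2 effects in knockdown samples (each
#' responder is active in a given line with probability `deg_carry_prob`,
#' so lines share most but not all of their differential genes); the target
#' gene itself (first gene) is always down by `knockdown_lfc`. True size
#' factors are drawn uniformly from `size_factor_range`.
#'
#' @param config a [sim_config()].
#' @return list with one element per cell line (each a list `counts`
#'   genes x samples integer matrix, `condition` character vector,
#'   `size_factors` true factors) plus `truth` (`target_gene`,
#'   `deg_effects` genes x lines matrix of active log2 effects, 0 =
#'   unaffected).
#' @export
simulate_counts <- function(config) {
  validate_sim_config(config)
  cc <- config$counts
  set.seed(substream_seed(config$seed, "counts"))
  gene_ids <- sprintf("CG%04d", seq_len(cc$n_genes))
  target <- gene_ids[1]
  n_deg <- round(cc$deg_fraction * cc$n_genes)
  deg_idx <- sort(sample(2:cc$n_genes, n_deg))
  deg_lfc <- runif(n_deg, cc$deg_lfc_range[1], cc$deg_lfc_range[2]) *
    rep_len(c(-1, 1), n_deg)
  lines <- paste0("CL", seq_len(cc$n_cell_lines))
  eff <- matrix(0, nrow = cc$n_genes, ncol = cc$n_cell_lines,
                dimnames = list(gene_ids, lines))
  out <- list()
  for (li in seq_len(cc$n_cell_lines)) {
    mu <- 2^rnorm(cc$n_genes, cc$mean_log2_mu, cc$sd_log2_mu)
    mu[1] <- 2^cc$mean_log2_mu  # the target is expressed at a typical level
    active <- runif(n_deg) < cc$deg_carry_prob
    eff[deg_idx[active], li] <- deg_lfc[active]
    eff[1, li] <- cc$knockdown_lfc
    nrep <- cc$n_replicates
    sf <- runif(2 * nrep, cc$size_factor_range[1], cc$size_factor_range[2])
    condition <- rep(c("knockdown", "control"), each = nrep)
    mu_mat <- outer(mu, sf) *
      2^(eff[, li] %o% as.numeric(condition == "knockdown"))
    counts <- matrix(rnbinom(length(mu_mat), mu = mu_mat,
                             size = 1 / cc$dispersion),
                     nrow = cc$n_genes,
                     dimnames = list(gene_ids,
                                     paste0(lines[li], "_", condition,
                                            "_", rep(seq_len(nrep), 2))))
    out[[lines[li]]] <- list(counts = counts, condition = condition,
                             size_factors = sf)
  }
  out$truth <- list(target_gene = target, deg_effects = eff)
  out
}

#' Simulate survival times with score-dependent hazard
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(gamma * score)`. Censoring is by an independent
#' exponential time with rate `baseline_hazard * c / (1 - c)`, which yields
#' exactly a fraction `c` censored when `gamma = 0` (and approximately `c`
#' otherwise); `c = 1` marks every patient censored, `c = 0` none.
#'
#' @param config a [sim_config()].
#' @param score optional per-patient continuous score (defaults to standard
#'   normal draws of length `n_patients`).
#' @return data.frame: `patient_id`, `time` (months), `event` (1 = event,
#'   0 = censored), `score`.
#' @export
simulate_survival <- function(config, score = NULL) {
  validate_sim_config(config)
  sv <- config$survival
  set.seed(substream_seed(config$seed, "survival"))
  if (is.null(score)) score <- rnorm(sv$n_patients)
  n <- length(score)
  tt <- rexp(n, rate = sv$baseline_hazard * exp(sv$gamma * score))
  cr <- sv$censoring_rate
  if (cr >= 1) {
    time <- tt; event <- rep(0L, n)
  } else if (cr <= 0) {
    time <- tt; event <- rep(1L, n)
  } else {
    cens <- rexp(n, rate = sv$baseline_hazard * cr / (1 - cr))
    time <- pmin(tt, cens)
    event <- as.integer(tt <= cens)
  }
  data.frame(patient_id = sprintf("P%04d", seq_len(n)), time = time,
             event = event, score = score, stringsAsFactors = FALSE)
}

#' Simulate a copy-number / expression coupling cohort
#'
#' Direct generator for calibrating the correlation filter: every gene gets
#' a recurrent-gain copy-number pattern (`amplitude * Bernoulli(penetrance)
#' + Gaussian(cn_noise_sd)` per sample); a fraction of genes is truly
#' coupled (`expression = slope * cn + noise`), the rest are null
#' (expression independent of copy number).
#'
#' @param seed integer seed.
#' @param n_genes,n_samples cohort shape.
#' @param frac_coupled fraction of genes with true positive coupling.
#' @param slope,noise_sd expression model for coupled genes.
#' @param penetrance,amplitude,cn_noise_sd copy-number pattern parameters.
#' @return list: `cn`, `expression` (genes x samples), `coupled` (gene ids
#'   with true coupling).
#' @export
simulate_coupling_cohort <- function(seed, n_genes = 1000, n_samples = 100,
                                     frac_coupled = 0.1, slope = 1.0,
                                     noise_sd = 0.5, penetrance = 0.6,
                                     amplitude = 1.0, cn_noise_sd = 0.3) {
  set.seed(substream_seed(seed, "coupling"))
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  coupled <- sort(sample.int(n_genes, round(frac_coupled * n_genes)))
  cn <- matrix(amplitude * (runif(n_genes * n_samples) < penetrance) +
               rnorm(n_genes * n_samples, 0, cn_noise_sd),
               nrow = n_genes,
               dimnames = list(gene_ids, sprintf("S%03d", seq_len(n_samples))))
  slope_g <- numeric(n_genes)
  slope_g[coupled] <- slope
  expr <- slope_g * cn + matrix(rnorm(n_genes * n_samples, 0, noise_sd),
                                nrow = n_genes, dimnames = dimnames(cn))
  list(cn = cn, expression = expr, coupled = gene_ids[coupled])
}

#' Write simulation truth labels as a JSON sidecar
#'
#' @param truth the `truth` element of a generator's output.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
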