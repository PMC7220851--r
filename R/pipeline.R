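# Config-driven end-to-end orchestration over the synthetic inputs:
# simulate -> call regions -> candidates -> screen -> deg -> survival.
# Every stage reads its inputs from and writes its outputs to the run
# directory, so stages can be re-run individually, and a manifest records
# parameters, seeds and output digests. Reruns with the same configuration
# are byte-identical.

#' Pipeline configuration with frozen analysis defaults
#'
#' Returns the nested configuration driving [run_pipeline()], pre-filled
#' with the analysis defaults: region-calling FDR 0.01, correlation FDR
#' 0.1, focal gene span 1-100, screen hit threshold 60% proliferation,
#' pool/single deconvolution thresholds 50% inhibition with the 2-of-4
#' rule, copy-number-gain panel filter at 8 lines, DEG thresholds p < 0.05
#' and |log2 FC| > 1 with baseMean >= 10, and the 2-of-3 common-DEG rule.
#' Unknown keys anywhere in the override list are rejected.
#'
#' @param seed root seed; cohort, screen, counts and survival substreams
#'   are derived from it.
#' @param ... named overrides of the default blocks (`sim`, `regions`,
#'   `candidates`, `screen`, `deg`, `survival`), each a list replacing
#'   individual entries.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, ...) {
  def <- list(
    seed = as.integer(seed),
    sim = list(n_samples_a = 100, n_samples_b = 100, n_chromosomes = 4,
               n_bins = 2000, bin_size = 1e5, n_genes = 1000,
               segment_noise_sd = 0.3, cn_expression_slope = 1.0,
               expression_noise_sd = 0.5),
    regions = list(fdr_level = 0.01, scales = c(0, 1, 2, 4, 8, 16),
                   n_permutations = 500),
    candidates = list(fdr_level = 0.1, min_genes = 1, max_genes = 100,
                      merge = "union"),
    screen = list(hit_threshold = 60, pool_threshold = 50,
                  single_threshold = 50, min_singles = 2,
                  cng_min_lines = 8, min_deconv_lines = 2),
    deg = list(p_cut = 0.05, lfc_cut = 1, base_mean_min = 10,
               min_lines = 2),
    survival = list(scan = c(20, 80), gamma = log(2),
                    censoring_rate = 0.3))
  user <- list(...)
  if (length(user)) {
    if (is.null(names(user)) || any(names(user) == ""))
      stop("overrides must be named")
    bad <- setdiff(names(user), names(def))
    if (length(bad)) stop("unknown config block(s): ",
                          paste(bad, collapse = ", "))
    for (blk in names(user)) {
      if (blk == "seed") { def$seed <- as.integer(user$seed); next }
      extra <- setdiff(names(user[[blk]]), names(def[[blk]]))
      if (length(extra))
        stop("unknown key(s) in config block '", blk, "': ",
             paste(extra, collapse = ", "))
      def[[blk]][names(user[[blk]])] <- user[[blk]]
    }
  }
  validate_pipeline_config(def)
  structure(def, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML file holds the same blocks as [pipeline_config()] (`seed`,
#' `sim`, `regions`, `candidates`, `screen`, `deg`, `survival`); omitted
#' entries fall back to the frozen defaults, and unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- if (is.null(y$seed)) 1 else y$seed
  do.call(pipeline_config,
          c(list(seed = seed), y[setdiff(names(y), "seed")]))
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

validate_pipeline_config <- function(cfg) {
  in_unit <- function(x) is.numeric(x) && length(x) == 1 && x > 0 && x < 1
  if (!in_unit(cfg$regions$fdr_level))
    stop("regions$fdr_level must lie in (0, 1)")
  if (!in_unit(cfg$candidates$fdr_level))
    stop("candidates$fdr_level must lie in (0, 1)")
  if (!in_unit(cfg$deg$p_cut)) stop("deg$p_cut must lie in (0, 1)")
  if (cfg$deg$lfc_cut < 0) stop("deg$lfc_cut must be >= 0")
  thr <- unlist(cfg$screen[c("hit_threshold", "pool_threshold",
                             "single_threshold")])
  if (any(thr <= 0 | thr >= 100))
    stop("screen thresholds must lie in (0, 100)")
  if (!cfg$candidates$merge %in% c("union", "intersection"))
    stop("candidates$merge must be 'union' or 'intersection'")
  sc <- cfg$survival$scan
  if (length(sc) != 2 || sc[1] < 20 || sc[2] > 80 || sc[1] >= sc[2])
    stop("survival$scan must be an increasing pair within [20, 80]")
  invisible(cfg)
}

# Read/write helpers shared by the stages.
pf <- function(outdir, name) file.path(outdir, name)

require_upstream <- function(outdir, file, stage, upstream) {
  if (!file.exists(pf(outdir, file)))
    stop(sprintf("stage '%s' requires '%s' from stage '%s'; run '%s' first",
                 stage, file, upstream, upstream))
}

stage_simulate <- function(cfg, outdir) {
  sims <- cfg$sim
  mk <- function(n, seed) {
    sim_config(seed = seed, n_samples = n,
               n_chromosomes = sims$n_chromosomes, n_bins = sims$n_bins,
               bin_size = sims$bin_size, n_genes = sims$n_genes,
               segment_noise_sd = sims$segment_noise_sd,
               cn_expression_slope = sims$cn_expression_slope,
               expression_noise_sd = sims$expression_noise_sd)
  }
  base <- substream_seed(cfg$seed, "pipeline")
  out <- character(0)
  for (co in c("A", "B")) {
    sc <- mk(if (co == "A") sims$n_samples_a else sims$n_samples_b,
             (base + match(co, c("A", "B"))) %% .Machine$integer.max)
    sim <- simulate_cohort(sc)
    write_seg(sim$cohort, pf(outdir, paste0("cohort_", co, ".seg")))
    write_matrix_tsv(sim$expression,
                     pf(outdir, paste0("expression_", co, ".tsv")))
    write_truth_json(sim$truth[c("driver_loci", "driver_genes")],
                     pf(outdir, paste0("truth_", co, ".json")))
    if (co == "A")
      write_annotation(sim$annotation, pf(outdir, "annotation_genes.tsv"),
                       pf(outdir, "annotation_chroms.tsv"))
    out <- c(out, paste0("cohort_", co, ".seg"),
             paste0("expression_", co, ".tsv"),
             paste0("truth_", co, ".json"))
  }
  c("annotation_genes.tsv", "annotation_chroms.tsv", out)
}

stage_regions <- function(cfg, outdir) {
  require_upstream(outdir, "cohort_A.seg", "regions", "simulate")
  ann <- read_annotation(pf(outdir, "annotation_genes.tsv"),
                         pf(outdir, "annotation_chroms.tsv"))
  out <- character(0)
  for (co in c("A", "B")) {
    cohort <- read_seg(pf(outdir, paste0("cohort_", co, ".seg")))
    binned <- segments_to_bins(cohort, ann, cfg$sim$bin_size)
    regs <- lapply(c("gain", "loss"), function(d) {
      call_recurrent_regions(binned, d, cfg$regions$fdr_level,
                             cfg$regions$scales,
                             cfg$regions$n_permutations,
                             seed = cfg$seed + match(co, c("A", "B")))
    })
    regs <- do.call(rbind, regs)
    write.table(regs, pf(outdir, paste0("regions_", co, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_regions_bed(regs, pf(outdir, paste0("regions_", co, ".bed")))
    out <- c(out, paste0("regions_", co, ".tsv"),
             paste0("regions_", co, ".bed"))
  }
  out
}

stage_candidates <- function(cfg, outdir) {
  require_upstream(outdir, "regions_A.tsv", "candidates", "regions")
  ann <- read_annotation(pf(outdir, "annotation_genes.tsv"),
                         pf(outdir, "annotation_chroms.tsv"))
  cands <- list()
  for (co in c("A", "B")) {
    regs <- read.delim(pf(outdir, paste0("regions_", co, ".tsv")),
                       stringsAsFactors = FALSE)
    regs <- regs[regs$direction == "gain", , drop = FALSE]
    focal <- filter_focal_regions(regs, ann, cfg$candidates$min_genes,
                                  cfg$candidates$max_genes)
    cohort <- read_seg(pf(outdir, paste0("cohort_", co, ".seg")))
    cn <- gene_level_cn(cohort, ann)
    expr <- read_matrix_tsv(pf(outdir, paste0("expression_", co, ".tsv")))
    sel <- select_candidates(focal, ann, cn, expr,
                             cfg$candidates$fdr_level, cohort = co)
    write.table(sel, pf(outdir, paste0("candidates_", co, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cands[[co]] <- sel
  }
  merged <- merge_cohort_candidates(cands$A, cands$B,
                                    mode = cfg$candidates$merge)
  write.table(merged, pf(outdir, "candidates_merged.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  c("candidates_A.tsv", "candidates_B.tsv", "candidates_merged.tsv")
}

stage_screen <- function(cfg, outdir) {
  require_upstream(outdir, "candidates_merged.tsv", "screen", "candidates")
  merged <- read.delim(pf(outdir, "candidates_merged.tsv"),
                       stringsAsFactors = FALSE)
  truth_a <- jsonlite::read_json(pf(outdir, "truth_A.json"),
                                 simplifyVector = TRUE)
  truth_b <- jsonlite::read_json(pf(outdir, "truth_B.json"),
                                 simplifyVector = TRUE)
  drivers <- union(truth_a$driver_genes, truth_b$driver_genes)
  genes <- merged$gene_id
  if (!length(genes)) genes <- sort(drivers)
  effects <- ifelse(genes %in% drivers, 0.6, 0.05)
  scfg <- sim_config(seed = cfg$seed, screen = list(n_genes = length(genes)))
  scr <- simulate_screen(scfg, gene_ids = genes, effects = effects)
  percents <- normalize_proliferation(scr$plates)
  hits <- call_primary_hits(percents, cfg$screen$hit_threshold)
  hit_sets <- split(hits$gene_id[hits$hit], hits$cell_line[hits$hit])
  merged_hits <- merge_hits(hit_sets)
  cng_kept <- cng_frequency_filter(scr$cna_status, cfg$screen$cng_min_lines)
  dperc <- normalize_deconv(scr$deconv)
  pool_pp <- dperc[dperc$sirna == "pool" &
                   dperc$gene_id %in% intersect(merged_hits$union, cng_kept), ]
  val <- validated_drivers(pool_pp, dperc, cfg$screen$single_threshold,
                           cfg$screen$pool_threshold,
                           cfg$screen$min_singles,
                           cfg$screen$min_deconv_lines)
  write.table(hits, pf(outdir, "screen_hits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(val, pf(outdir, "screen_validated.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_per_line = as.list(merged_hits$n_per_line),
         n_union = merged_hits$n_union,
         n_intersection = merged_hits$n_intersection,
         cng_filtered = cng_kept,
         validated = val$gene_id[val$validated]),
    pf(outdir, "screen_summary.json"), auto_unbox = TRUE, digits = NA)
  c("screen_hits.tsv", "screen_validated.tsv", "screen_summary.json")
}

# Deconvolution plates share the screen's control wells per cell line.
normalize_deconv <- function(deconv) {
  out <- list()
  for (cl in unique(deconv$cell_line)) {
    d <- deconv[deconv$cell_line == cl, , drop = FALSE]
    cm <- mean(d$raw[d$is_control])
    if (!is.finite(cm) || cm <= 0)
      stop("deconvolution plate rejected: control mean <= 0 for ", cl)
    d$percent_proliferation <- 100 * d$raw / cm
    out[[cl]] <- d
  }
  do.call(rbind, out)
}

stage_deg <- function(cfg, outdir) {
  ccfg <- sim_config(seed = cfg$seed)
  sims <- simulate_counts(ccfg)
  lines <- setdiff(names(sims), "truth")
  down <- list(); up <- list(); out <- character(0)
  for (li in lines) {
    s <- sims[[li]]
    res <- nb_wald_test(s$counts, s$condition, reference = "control",
                        base_mean_min = cfg$deg$base_mean_min)
    degs <- call_degs(res, cfg$deg$p_cut, cfg$deg$lfc_cut)
    res$direction <- ifelse(res$gene_id %in% degs$down, "down",
                            ifelse(res$gene_id %in% degs$up, "up", "ns"))
    f <- paste0("deg_", li, ".tsv")
    write.table(res, pf(outdir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
    down[[li]] <- degs$down; up[[li]] <- degs$up
    out <- c(out, f)
  }
  common <- common_degs(down, up, cfg$deg$min_lines)
  jsonlite::write_json(common, pf(outdir, "deg_common.json"),
                       auto_unbox = TRUE, digits = NA)
  c(out, "deg_common.json")
}

stage_survival <- function(cfg, outdir) {
  require_upstream(outdir, "expression_A.tsv", "survival", "simulate")
  require_upstream(outdir, "screen_validated.tsv", "survival", "screen")
  expr <- read_matrix_tsv(pf(outdir, "expression_A.tsv"))
  val <- read.delim(pf(outdir, "screen_validated.tsv"),
                    stringsAsFactors = FALSE)
  gene <- if (any(val$validated)) val$gene_id[val$validated][1] else
    rownames(expr)[1]
  score <- as.numeric(scale(expr[gene, ]))
  svcfg <- sim_config(seed = cfg$seed,
                      survival = list(n_patients = length(score),
                                      gamma = cfg$survival$gamma,
                                      censoring_rate =
                                        cfg$survival$censoring_rate))
  surv <- simulate_survival(svcfg, score = score)
  split <- best_cutoff_split(surv$time, surv$event, surv$score,
                             cfg$survival$scan)
  grp <- factor(ifelse(split$high, "high", "low"), c("low", "high"))
  hr <- hazard_ratio(surv$time, surv$event, grp)
  km_high <- km_curve(surv$time[split$high], surv$event[split$high])
  km_low <- km_curve(surv$time[!split$high], surv$event[!split$high])
  write.table(surv, pf(outdir, "survival.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(rbind(cbind(group = "high", km_high),
                    cbind(group = "low", km_low)),
              pf(outdir, "survival_km.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(score_gene = gene, cutoff = split$cutoff,
         logrank_p = split$p, cutoff_optimized = split$cutoff_optimized,
         hr = hr$hr, hr_lower = hr$lower, hr_upper = hr$upper),
    pf(outdir, "survival_summary.json"), auto_unbox = TRUE, digits = NA)
  c("survival.tsv", "survival_km.tsv", "survival_summary.json")
}

#' Run the end-to-end pipeline
#'
#' Executes the requested stages in dependency order -- `simulate`,
#' `regions`, `candidates`, `screen`, `deg`, `survival` -- against a run
#' directory, then writes `manifest.json` recording the package version,
#' the configuration, and an md5 digest of every stage output. Stage
#' outputs are plain TSV/BED/JSON files that can be re-used individually;
#' a rerun with the same configuration is byte-identical. A stage whose
#' upstream output is missing fails with an error naming the stage to run
#' first.
#'
#' @param config a [pipeline_config()].
#' @param outdir run directory (created if absent).
#' @param stages character vector of stages to run (default: all six).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("simulate", "regions", "candidates",
                                    "screen", "deg", "survival")) {
  validate_pipeline_config(config)
  all_stages <- c(simulate = stage_simulate, regions = stage_regions,
                  candidates = stage_candidates, screen = stage_screen,
                  deg = stage_deg, survival = stage_survival)
  bad <- setdiff(stages, names(all_stages))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- names(all_stages)[names(all_stages) %in% stages]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "ampdriver",
                   version = as.character(packageVersion("ampdriver")),
                   seed = config$seed,
                   config = unclass(config), stages = list())
  for (st in stages) {
    files <- all_stages[[st]](config, outdir)
    digests <- as.list(tools::md5sum(vapply(files, function(f)
      pf(outdir, f), character(1))))
    names(digests) <- files
    manifest$stages[[st]] <- list(name = st, outputs = digests)
  }
  jsonlite::write_json(manifest, pf(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
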