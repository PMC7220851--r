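#!/usr/bin/env Rscript
# Stage 1: simulate the two tumor cohorts.
#
# Two independent cohorts (A and B, 100 samples each) of segmented somatic
# copy-number profiles over 2,000 bins of 100 kb on 4 chromosomes, each
# carrying three focal gain loci at penetrance 0.6 and +1 log2 unit over
# segment-level noise (sd 0.3), plus log2 expression for 1,000 genes in
# which only the genes inside the gain loci are coupled to their copy
# number (slope 1, residual sd 0.5). Written as SEG / TSV with JSON truth
# sidecars under results/run/.

source("analysis/00_config.R")

run_pipeline(CFG, RUN_DIR, stages = "simulate")

for (co in c("A", "B")) {
  cohort <- read_seg(file.path(RUN_DIR, paste0("cohort_", co, ".seg")))
  truth <- jsonlite::read_json(file.path(RUN_DIR,
                                         paste0("truth_", co, ".json")),
                               simplifyVector = TRUE)
  message(sprintf(
    "cohort %s: %d samples, %d segments, %d driver loci containing %d genes",
    co, length(unique(cohort$sample)), nrow(cohort),
    nrow(truth$driver_loci), length(truth$driver_genes)))
}
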