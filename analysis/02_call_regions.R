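#!/usr/bin/env Rscript
# Stage 2: call recurrent copy-number regions in each cohort.
#
# Bins each cohort, aggregates the rectified log2 ratios, and calls gain
# and loss regions at FDR 0.01 with 500 cyclic-shift permutations over the
# dyadic scale space {0, 1, 2, 4, 8, 16}. Regions land in
# results/run/regions_{A,B}.{tsv,bed}.

source("analysis/00_config.R")

run_pipeline(CFG, RUN_DIR, stages = "regions")

for (co in c("A", "B")) {
  regs <- read.delim(file.path(RUN_DIR, paste0("regions_", co, ".tsv")))
  truth <- jsonlite::read_json(file.path(RUN_DIR,
                                         paste0("truth_", co, ".json")),
                               simplifyVector = TRUE)
  gains <- regs[regs$direction == "gain", ]
  hit <- region_truth_overlap(gains, truth$driver_loci)
  message(sprintf(
    "cohort %s: %d gain regions (%d leaves, %d overlapping a true locus), %d loss regions",
    co, nrow(gains), sum(gains$is_leaf), sum(hit),
    sum(regs$direction == "loss")))
}
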