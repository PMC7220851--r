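#!/usr/bin/env Rscript
# Stage 3: focal filtering and the copy-number/expression correlation
# filter.
#
# Keeps leaf gain regions spanning 1-100 genes, tests each contained
# gene's Spearman correlation between gene-level copy number and
# expression, adjusts by Benjamini-Hochberg at FDR 0.1 within each
# cohort's tested set, and merges the two cohorts' candidate lists by
# union. Candidate tables land in results/run/candidates_*.tsv.

source("analysis/00_config.R")

run_pipeline(CFG, RUN_DIR, stages = "candidates")

merged <- read.delim(file.path(RUN_DIR, "candidates_merged.tsv"))
truth <- lapply(c("A", "B"), function(co)
  jsonlite::read_json(file.path(RUN_DIR, paste0("truth_", co, ".json")),
                      simplifyVector = TRUE))
drivers <- unique(unlist(lapply(truth, `[[`, "driver_genes")))

for (co in c("A", "B")) {
  sel <- read.delim(file.path(RUN_DIR, paste0("candidates_", co, ".tsv")))
  message(sprintf("cohort %s: %d candidate genes (median rho %.2f)",
                  co, nrow(sel), median(sel$spearman_rho)))
}
message(sprintf(
  "merged: %d unique candidates; %d/%d embedded driver genes recovered",
  nrow(merged), sum(drivers %in% merged$gene_id), length(drivers)))
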