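#!/usr/bin/env Rscript
# Stage 4: siRNA loss-of-function screen of the candidate genes.
#
# Simulates duplicate proliferation screens of the merged candidate list
# in two cell lines (true drivers inhibit proliferation by 60%, passengers
# by 5%), normalizes to the non-targeting controls, calls hits at <60%
# proliferation, filters by copy-number-gain frequency across the 20-line
# panel (>= 8 lines), and validates hits by pooled inhibition in all lines
# plus the 2-of-4 single-siRNA deconvolution rule.

source("analysis/00_config.R")

run_pipeline(CFG, RUN_DIR, stages = "screen")

hits <- read.delim(file.path(RUN_DIR, "screen_hits.tsv"))
summ <- jsonlite::read_json(file.path(RUN_DIR, "screen_summary.json"),
                            simplifyVector = TRUE)
for (cl in names(summ$n_per_line))
  message(sprintf("%s: %d primary hits", cl, summ$n_per_line[[cl]]))
message(sprintf("union %d, common %d; %d pass the CNG-frequency filter",
                summ$n_union, summ$n_intersection,
                length(summ$cng_filtered)))
message(sprintf("validated drivers (all-line inhibition + deconvolution): %s",
                paste(summ$validated, collapse = ", ")))
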