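#!/usr/bin/env Rscript
# Stage 5: knockdown differential expression across three cell lines.
#
# Simulates negative-binomial count matrices (3 knockdown vs 3 control
# samples per line, target gene down 2-fold), normalizes with
# median-of-ratios size factors, tests each gene with the NB Wald test
# (baseMean >= 10), calls DEGs at p < 0.05 and |log2 FC| > 1, and applies
# the at-least-2-of-3-lines common-DEG rule.

source("analysis/00_config.R")

run_pipeline(CFG, RUN_DIR, stages = "deg")

for (li in c("CL1", "CL2", "CL3")) {
  d <- read.delim(file.path(RUN_DIR, paste0("deg_", li, ".tsv")))
  tg <- d[d$gene_id == "CG0001", ]
  message(sprintf(
    "%s: %d tested, %d down / %d up; target log2FC = %.2f (p = %.2g)",
    li, nrow(d), sum(d$direction == "down"), sum(d$direction == "up"),
    tg$log2FoldChange, tg$pvalue))
}
common <- jsonlite::read_json(file.path(RUN_DIR, "deg_common.json"),
                              simplifyVector = TRUE)
message(sprintf("common DEGs: %d down + %d up = %d total",
                common$n_down, common$n_up, common$total))
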