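# Shared configuration for the analysis scripts. Every script sources this
# file, so the whole workflow is driven by one seed and one run directory.

library(ampdriver)

RUN_DIR <- "results/run"
CFG <- pipeline_config(seed = 42)
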