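# Shared configuration for the numbered analysis drivers.
# Outputs go under results/pipeline; everything is deterministic under SEED.

library(tmmflow)

SEED <- 1L
OUT <- file.path("results", "pipeline")

analysis_config <- function(gmt = NULL) {
  pipeline_config(out_dir = OUT, seed = SEED, gmt = gmt,
                  synthetic = synthetic_config(seed = SEED))
}
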