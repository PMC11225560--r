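# Stage 2: fold changes and PSF activities.
#
# Counts are median-of-ratios normalized, log2-transformed with pseudocount
# 1, gene-wise mean-centered and de-logged; the fold changes are propagated
# through the packaged TEL and ALT pathway graphs to per-sample pathway and
# branch activities.

source(file.path("analysis", "00_config.R"))

run_pipeline(analysis_config(), stages = "psf")

truth <- read.delim(file.path(OUT, "truth.tsv"))
for (pw in c("tel", "alt")) {
  act <- read.delim(file.path(OUT, paste0("psf_", pw, ".tsv")),
                    check.names = FALSE)
  lvl <- if (pw == "alt") sub("^ALT_([a-z]+)_.*", "\\1", truth$phenotype)
         else sub("^.*_TEL_([a-z]+)$", "\\1", truth$phenotype)
  med <- tapply(act$log10_activity, lvl, median)
  cat(sprintf("%s median log10 PSF by true axis level: low %.3f, middle %.3f, high %.3f\n",
              toupper(pw), med[["low"]], med[["middle"]], med[["high"]]))
}
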