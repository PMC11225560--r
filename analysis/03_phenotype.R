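# Stage 3: segmented thresholds and TMM phenotype calls.
#
# Two-breakpoint segmented regressions on the pooled log10 activity
# distributions give per-axis low/middle/high thresholds; the 3x3 grid
# collapses to the five TMM phenotypes.  Agreement against the implanted
# truth is reported (see the methods vignette for why the middle class is
# systematically over-called on cluster-separated synthetic cohorts).

source(file.path("analysis", "00_config.R"))

run_pipeline(analysis_config(), stages = "phenotype")

calls <- read.delim(file.path(OUT, "phenotypes.tsv"))
thr <- jsonlite::read_json(file.path(OUT, "thresholds.json"))
truth <- read.delim(file.path(OUT, "truth.tsv"))

cat(sprintf("ALT thresholds (log10): %.3f / %.3f; TEL: %.3f / %.3f\n",
            thr$ALT$t_low, thr$ALT$t_high, thr$TEL$t_low, thr$TEL$t_high))
print(phenotype_prevalence(calls))
agree <- mean(calls$phenotype == truth$phenotype[match(calls$sample,
                                                       truth$sample)])
cat(sprintf("agreement with implanted truth: %.3f\n", agree))
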