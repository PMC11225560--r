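# Stage 1: draw the synthetic study cohort.
#
# 500 samples (100 per TMM phenotype), 63 pathway genes + 2000 background
# genes, negative-binomial counts (dispersion 0.1) with 2-fold activation /
# suppression of pathway genes by the true phenotype, MSI labels enriched in
# high-activity truths, and exponential survival (HR 2 for the double-high
# versus double-low phenotype) with ~30% uniform censoring.

source(file.path("analysis", "00_config.R"))

run_pipeline(analysis_config(), stages = "simulate")

truth <- read.delim(file.path(OUT, "truth.tsv"))
cohort <- read.delim(file.path(OUT, "cohort.tsv"))
cat("samples per phenotype:\n")
print(table(truth$phenotype))
cat(sprintf("MSI-H rate, high-activity truths: %.2f; others: %.2f\n",
            mean(cohort$msi[grepl("high", truth$phenotype)] == "MSI-H"),
            mean(cohort$msi[!grepl("high", truth$phenotype)] == "MSI-H")))
cat(sprintf("overall censoring: %.2f\n", mean(1 - cohort$os_event)))
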