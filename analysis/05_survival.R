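# Stage 5: survival by TMM phenotype.
#
# Kaplan-Meier curves per phenotype, global and pairwise log-rank tests
# (BH-adjusted), and Cox hazard ratios against the ALT_low_TEL_low
# reference, for overall and progression-free survival.

source(file.path("analysis", "00_config.R"))

run_pipeline(analysis_config(), stages = "survival")

gl <- jsonlite::read_json(file.path(OUT, "survival_logrank.json"))
cat(sprintf("global log-rank: OS chi-square %.2f (p = %.3g), PFS chi-square %.2f (p = %.3g)\n",
            gl$os$chisq, gl$os$p, gl$pfs$chisq, gl$pfs$p))
hr <- read.delim(file.path(OUT, "survival_os_cox.tsv"))
cat("OS hazard ratios vs ALT_low_TEL_low:\n")
print(hr[, c("term", "HR", "lower", "upper", "p")])
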