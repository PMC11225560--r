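# Stage 4: MSI/MSS comparisons of pathway and branch activity.
#
# Kruskal-Wallis across MSS / MSI-L / MSI-H on the TEL and ALT pathway
# activities and on every branch activity, with Dunn's post hoc pairwise
# tests (BH-adjusted).

source(file.path("analysis", "00_config.R"))

run_pipeline(analysis_config(), stages = "msi")

kw <- read.delim(file.path(OUT, "msi_kruskal.tsv"))
cat("pathway-level Kruskal-Wallis:\n")
print(kw[kw$level == "pathway", ])
dunn <- read.delim(file.path(OUT, "msi_dunn.tsv"))
sig <- dunn[dunn$p_adjusted < 0.05 & dunn$level != "pathway", ]
cat(sprintf("branch-level Dunn pairs with adjusted p < 0.05: %d of %d\n",
            nrow(sig), sum(dunn$level != "pathway")))
print(head(sig[order(sig$p_adjusted),
               c("pathway", "level", "group1", "group2", "p_adjusted")], 8))
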