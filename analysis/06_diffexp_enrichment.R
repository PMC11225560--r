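# Stage 6: differential expression, recurrence tallies, over-representation.
#
# Each phenotype is contrasted against ALT_low_TEL_low per synthetic cancer
# type; genes recurrently significant across cancer types are tallied and
# tested for over-representation against a small GMT collection built from
# the packaged pathway gene sets (stand-in for a user-supplied database).

source(file.path("analysis", "00_config.R"))

gmt <- file.path(OUT, "synthetic_sets.gmt")
dir.create(OUT, recursive = TRUE, showWarnings = FALSE)
alt_genes <- pathway_genes(tmm_pathway("ALT"))
tel_genes <- pathway_genes(tmm_pathway("TEL"))
writeLines(c(
  paste(c("alt_pathway", "synthetic", alt_genes), collapse = "\t"),
  paste(c("tel_pathway", "synthetic", tel_genes), collapse = "\t"),
  paste(c("background_decoy", "synthetic", sprintf("BG%04d", 1:40)),
        collapse = "\t")), gmt)

run_pipeline(analysis_config(gmt = gmt), stages = c("diffexp", "enrich"))

up <- read.delim(file.path(OUT, "recurrence_up_ALT_high_TEL_high.tsv"))
cat("most recurrently upregulated genes, ALT_high_TEL_high vs reference:\n")
print(head(up, 8))
ora <- read.delim(file.path(OUT, "ora_ALT_high_TEL_high.tsv"))
cat("over-representation of recurrent genes:\n")
print(ora)
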