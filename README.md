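# tmmflow

Topology-based scoring and phenotyping of telomere maintenance mechanisms
(TMMs) from RNA-seq counts.

Cancers escape replicative senescence by maintaining their telomeres, via
telomerase (TEL: TERT/TERC, dyskerin, telomerase assembly and recruitment)
or by alternative lengthening of telomeres (ALT: DNA damage response, APB
formation, telomere recruitment to APBs, strand invasion, templated
synthesis, Holliday junction processing). `tmmflow` quantifies the
transcriptional activity of both pathways per sample and stratifies cohorts
into five TMM phenotypes, for anyone analyzing bulk or single-cell tumor
RNA-seq cohorts with clinical annotations.

## The method

1. **Fold changes.** Counts are normalized by median-of-ratios size factors
   (rescaled to geometric mean 1), transformed as `log2(count/sf + 1)`,
   centered per gene on the cohort mean, and de-logged, giving a positive
   FC matrix with gene-wise geometric mean 1.
2. **Pathway signal flow (PSF).** FC values propagate once, in topological
   order, through signed pathway graphs. A node's own expression is the
   geometric mean of its genes' FC; an activating edge contributes
   `w * v(src)`, an inhibiting edge `w / v(src)`; ordinary nodes combine
   incoming contributions by their mean, complexes by the minimum; the
   combined signal is multiplied by the node's own expression. The sink
   value is the pathway activity; branch-tagged nodes give branch
   activities. Packaged TEL (26 genes) and ALT (37 genes) graph
   reconstructions ship as editable JSON.
3. **Phenotyping.** Two-breakpoint segmented regressions on the pooled
   log10 activity distributions give per-axis low/middle/high thresholds;
   the 3x3 grid collapses to five phenotypes (`ALT_high_TEL_low`,
   `ALT_low_TEL_low`, `ALT_middle_TEL_middle`, `ALT_high_TEL_high`,
   `ALT_low_TEL_high` — any middle cell collapses to middle/middle).
4. **Downstream.** Kruskal-Wallis and Dunn tests across MSI groups at
   pathway and branch level; Kaplan-Meier, pairwise log-rank and Cox hazard
   ratios by phenotype; per-cancer differential expression against the
   `ALT_low_TEL_low` reference with cross-cancer recurrence tallies and
   hypergeometric gene-set over-representation (GMT input).

A negative-binomial synthetic-cohort generator with implanted phenotype
truth, MSI enrichment and phenotype-dependent survival makes the whole
pipeline testable without downloads. See `vignettes/tmm-psf-phenotyping.Rmd`
for the model details and design rationale.

## Worked example

The numbered drivers under `analysis/` run the whole study on a synthetic
cohort (500 samples, 100 per phenotype; outputs under `results/pipeline/`):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_psf.R
Rscript analysis/03_phenotype.R   # thresholds + phenotype calls
Rscript analysis/05_survival.R    # log-rank + Cox by phenotype
```

`03_phenotype.R` prints (seed 1):

```
ALT thresholds (log10): -0.539 / 0.508; TEL: -0.312 / 0.229
              phenotype count fraction
1      ALT_high_TEL_low    77    0.154
2       ALT_low_TEL_low    67    0.134
3 ALT_middle_TEL_middle   209    0.418
4     ALT_high_TEL_high    67    0.134
5      ALT_low_TEL_high    80    0.160
agreement with implanted truth: 0.782
```

i.e. the fitted thresholds cut each log10 activity axis into low/middle/high
and the middle class absorbs borderline corner samples (the vignette
explains why least-squares knee-finding over-calls the middle on
cluster-separated synthetic data). `05_survival.R` then recovers the
implanted survival disadvantage of the active phenotypes:

```
global log-rank: OS chi-square 12.90 (p = 0.0118), PFS chi-square 17.14 (p = 0.00182)
OS hazard ratios vs ALT_low_TEL_low:
                   term       HR    lower    upper            p
1     ALT_high_TEL_high 1.765571 1.151573 2.706944 0.0091277764
2      ALT_high_TEL_low 2.064212 1.358668 3.136140 0.0006830431
3      ALT_low_TEL_high 1.824858 1.199926 2.775261 0.0049229831
4 ALT_middle_TEL_middle 1.696862 1.176406 2.447576 0.0046661861
```

Real data enter through `pipeline_config(counts = "counts.tsv", cohort =
"clinical.tsv")` (TSV counts, first column gene symbols) or
`read_counts_mtx()` for single-cell triplets, then the same stages.

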