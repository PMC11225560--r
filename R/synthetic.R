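#' Configuration for the synthetic TMM cohort generator
#'
#' Defines the study conditions the generator emulates: negative-binomial
#' counts with sample-specific library sizes, per-pathway multiplicative
#' activation of pathway genes defining ground-truth phenotypes, MSI labels
#' enriched in high-activity phenotypes, and phenotype-dependent exponential
#' survival with independent uniform censoring.
#'
#' Per phenotype, each axis at truth level `low`/`middle`/`high` multiplies
#' the NB mean of every gene of that pathway (i.e. of every branch) by
#' `1/effect_size`, `1`, or `effect_size`.
#'
#' @param n_per_phenotype Named integer vector, samples per phenotype
#'   (default 100 each).
#' @param n_background_genes Genes outside the two pathways.
#' @param nb_dispersion NB dispersion: `var = mu + dispersion * mu^2`.
#' @param base_mean Baseline NB mean per gene.
#' @param library_size_range Uniform range of per-sample library-size
#'   multipliers.
#' @param effect_size Fold multiplier separating high (and `1/effect_size`
#'   low) pathway-gene means from baseline.
#' @param msi_enrichment P(MSI-H) for phenotypes with a high axis.
#' @param msi_baseline P(MSI-H) otherwise.
#' @param survival_hazards Named vector of exponential event rates per day,
#'   one per phenotype.
#' @param censoring_rate Target fraction censored (uniform censoring horizon
#'   solved from it at the mean hazard).
#' @param n_cancer_types Synthetic cancer-type labels assigned round-robin.
#' @param seed Integer seed; generation is deterministic given the config.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_per_phenotype = NULL,
                             n_background_genes = 2000,
                             nb_dispersion = 0.1,
                             base_mean = 100,
                             library_size_range = c(0.5, 1.5),
                             effect_size = 2,
                             msi_enrichment = 0.4,
                             msi_baseline = 0.05,
                             survival_hazards = NULL,
                             censoring_rate = 0.3,
                             n_cancer_types = 3,
                             seed = 1L) {
  if (is.null(n_per_phenotype)) {
    n_per_phenotype <- stats::setNames(rep(100L, 5), TMM_PHENOTYPES)
  }
  if (is.null(survival_hazards)) {
    survival_hazards <- c(ALT_high_TEL_low = 1e-3,
                          ALT_low_TEL_low = 5e-4,
                          ALT_middle_TEL_middle = 7.5e-4,
                          ALT_high_TEL_high = 1e-3,
                          ALT_low_TEL_high = 7e-4)
  }
  stopifnot(all(names(n_per_phenotype) %in% TMM_PHENOTYPES),
            all(n_per_phenotype >= 0), sum(n_per_phenotype) > 0,
            nb_dispersion > 0, base_mean > 0, effect_size > 0,
            length(library_size_range) == 2,
            all(library_size_range > 0),
            msi_enrichment >= 0, msi_enrichment <= 1,
            msi_baseline >= 0, msi_baseline <= 1,
            all(survival_hazards > 0),
            censoring_rate >= 0, censoring_rate < 1)
  structure(list(n_per_phenotype = n_per_phenotype,
                 n_background_genes = n_background_genes,
                 nb_dispersion = nb_dispersion,
                 base_mean = base_mean,
                 library_size_range = library_size_range,
                 effect_size = effect_size,
                 msi_enrichment = msi_enrichment,
                 msi_baseline = msi_baseline,
                 survival_hazards = survival_hazards,
                 censoring_rate = censoring_rate,
                 n_cancer_types = n_cancer_types,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

axis_multiplier <- function(level, effect) {
  switch(level, low = 1 / effect, middle = 1, high = effect)
}

censoring_horizon <- function(rate, hazard) {
  if (rate <= 0) return(Inf)
  # P(censored) for C ~ U(0, tau), T ~ Exp(hazard): (1 - exp(-h tau)) / (h tau)
  f <- function(tau) (1 - exp(-hazard * tau)) / (hazard * tau) - rate
  stats::uniroot(f, lower = 1e-6 / hazard, upper = 1e3 / hazard)$root
}

#' Generate a synthetic cohort with ground-truth TMM phenotypes
#'
#' Draws a gene x sample count matrix (two pathways' genes plus background
#' genes), a clinical table and a truth table.  Per sample: a library-size
#' multiplier uniform in the configured range; per gene a negative-binomial
#' count with mean `base_mean x axis multiplier x library size` for pathway
#' genes (multiplier from the sample's true phenotype) and
#' `base_mean x library size` otherwise.  MSI-H labels are enriched in
#' phenotypes with a high axis; survival times are exponential at the
#' phenotype's hazard with independent uniform censoring.  Deterministic
#' under the config seed.
#'
#' @param config A [synthetic_config()].
#' @param tel_graph,alt_graph Validated `tmm_pathway` objects (defaults: the
#'   packaged reconstructions).
#' @return List: `counts` (matrix), `cohort` (clinical data frame: `sample`,
#'   `cancer_type`, `tissue`, `msi`, `purity`, `os_time`, `os_event`,
#'   `pfs_time`, `pfs_event`), `truth` (`sample`, `phenotype`, `alt_mult`,
#'   `tel_mult`, `hazard`).
#' @export
generate_cohort <- function(config = synthetic_config(),
                            tel_graph = tmm_pathway("TEL"),
                            alt_graph = tmm_pathway("ALT")) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  npp <- config$n_per_phenotype[config$n_per_phenotype > 0]
  phen <- rep(names(npp), npp)
  n <- length(phen)
  samples <- sprintf("S%04d", seq_len(n))

  tel_genes <- pathway_genes(tel_graph)
  alt_genes <- setdiff(pathway_genes(alt_graph), tel_genes)
  bg_genes <- sprintf("BG%04d", seq_len(config$n_background_genes))
  genes <- c(alt_genes, tel_genes, bg_genes)

  alt_level <- sub("^ALT_([a-z]+)_TEL_.*$", "\\1", phen)
  tel_level <- sub("^.*_TEL_([a-z]+)$", "\\1", phen)
  alt_mult <- vapply(alt_level, axis_multiplier, numeric(1),
                     effect = config$effect_size)
  tel_mult <- vapply(tel_level, axis_multiplier, numeric(1),
                     effect = config$effect_size)

  lib <- stats::runif(n, config$library_size_range[1],
                      config$library_size_range[2])
  mu <- matrix(config$base_mean, nrow = length(genes), ncol = n,
               dimnames = list(genes, samples))
  mu[alt_genes, ] <- sweep(mu[alt_genes, , drop = FALSE], 2, alt_mult, "*")
  mu[tel_genes, ] <- sweep(mu[tel_genes, , drop = FALSE], 2, tel_mult, "*")
  mu <- sweep(mu, 2, lib, "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$nb_dispersion),
                   nrow = nrow(mu), dimnames = dimnames(mu))

  high_activity <- alt_level == "high" | tel_level == "high"
  p_msih <- ifelse(high_activity, config$msi_enrichment, config$msi_baseline)
  u <- stats::runif(n)
  msi <- ifelse(u < p_msih, "MSI-H",
                ifelse(u < p_msih + 0.2 * (1 - p_msih), "MSI-L", "MSS"))

  hazard <- config$survival_hazards[phen]
  horizon <- censoring_horizon(config$censoring_rate,
                               mean(config$survival_hazards))
  os_t <- stats::rexp(n, rate = hazard)
  os_c <- if (is.finite(horizon)) stats::runif(n, 0, horizon) else rep(Inf, n)
  pfs_t <- stats::rexp(n, rate = 1.5 * hazard)
  pfs_c <- if (is.finite(horizon)) stats::runif(n, 0, horizon) else rep(Inf, n)

  cohort <- data.frame(
    sample = samples,
    cancer_type = paste0("SYN", (seq_len(n) - 1L) %% config$n_cancer_types + 1L),
    tissue = "tumor",
    msi = msi,
    purity = stats::runif(n, 0.3, 1),
    os_time = pmin(os_t, os_c),
    os_event = as.integer(os_t <= os_c),
    pfs_time = pmin(pfs_t, pfs_c),
    pfs_event = as.integer(pfs_t <= pfs_c),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(sample = samples,
                      phenotype = phen,
                      alt_mult = unname(alt_mult),
                      tel_mult = unname(tel_mult),
                      hazard = unname(hazard),
                      stringsAsFactors = FALSE)
  list(counts = counts, cohort = cohort, truth = truth)
}

#' Simulate a protein-level table coupled to an expression matrix
#'
#' Protein abundance per gene and sample is a linear transform of the
#' size-factor-normalized `log2(count + 1)` expression plus Gaussian noise,
#' emulating the structure of reverse-phase protein array data used for
#' protein-versus-RNA correlation.  With `noise_sd = 0` the correlation with
#' log2 expression is exactly 1.
#'
#' @param counts Gene x sample count matrix.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed.
#' @param slope,intercept True linear transform, recorded in the result.
#' @return List: `protein` (matrix), `log2_expression` (matrix), `slope`,
#'   `intercept`, `noise_sd`.
#' @export
generate_protein_table <- function(counts, noise_sd = 0.5, seed = 1L,
                                   slope = 1, intercept = 0) {
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  set.seed(seed)
  f <- size_factors(counts)
  x <- log2(sweep(counts, 2, f, "/") + 1)
  protein <- intercept + slope * x +
    matrix(stats::rnorm(length(x), sd = noise_sd), nrow = nrow(x))
  dimnames(protein) <- dimnames(counts)
  list(protein = protein, log2_expression = x,
       slope = slope, intercept = intercept, noise_sd = noise_sd)
}
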