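PIPELINE_STAGES <- c("simulate", "psf", "phenotype", "msi", "survival",
                     "diffexp", "enrich")

#' Pipeline run configuration
#'
#' One structured object drives [run_pipeline()].  Leave `counts`/`cohort`
#' as `NULL` to run on a synthetic cohort generated by the `simulate` stage;
#' point them at TSV files to analyze real data (then skip `simulate`).
#'
#' @param out_dir Output directory (created if needed).
#' @param counts Optional path to a gene x sample count TSV.
#' @param cohort Optional path to a clinical TSV (columns `sample`,
#'   `cancer_type`, `msi`, `os_time`, `os_event`, `pfs_time`, `pfs_event`,
#'   optionally `purity`).
#' @param tel_pathway,alt_pathway Optional pathway JSON paths; default: the
#'   packaged reconstructions.
#' @param gmt Optional GMT file for the `enrich` stage.
#' @param pseudocount Pseudocount for the fold-change transform.
#' @param scope Thresholding scope, `"pooled"` or `"per_stratum"`.
#' @param alpha DE significance level (adjusted p).
#' @param q_cutoff Over-representation q-value cutoff.
#' @param seed Seed recorded in every manifest and used by `simulate`.
#' @param synthetic A [synthetic_config()] for the `simulate` stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            counts = NULL, cohort = NULL,
                            tel_pathway = NULL, alt_pathway = NULL,
                            gmt = NULL,
                            pseudocount = 1,
                            scope = c("pooled", "per_stratum"),
                            alpha = 0.05, q_cutoff = 0.05,
                            seed = 1L,
                            synthetic = NULL) {
  scope <- match.arg(scope)
  for (p in c(counts, cohort, tel_pathway, alt_pathway, gmt)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("configured input does not exist: ", p, call. = FALSE)
    }
  }
  if (is.null(synthetic)) synthetic <- synthetic_config(seed = seed)
  structure(list(out_dir = out_dir, counts = counts, cohort = cohort,
                 tel_pathway = tel_pathway, alt_pathway = alt_pathway,
                 gmt = gmt, pseudocount = pseudocount, scope = scope,
                 alpha = alpha, q_cutoff = q_cutoff, seed = as.integer(seed),
                 synthetic = synthetic),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(unclass(config)), tf)
  unname(tools::md5sum(tf))
}

write_manifest <- function(config, stage, inputs, outputs) {
  checksum <- function(fs) {
    fs <- fs[file.exists(fs)]
    as.list(stats::setNames(unname(tools::md5sum(fs)), basename(fs)))
  }
  manifest <- list(stage = stage,
                   config_hash = config_hash(config),
                   seed = config$seed,
                   package_version = as.character(utils::packageVersion("tmmflow")),
                   inputs = checksum(inputs),
                   outputs = checksum(outputs))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir,
                                 paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

artifact <- function(config, name) file.path(config$out_dir, name)

require_artifacts <- function(config, stage, files) {
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop(sprintf("stage '%s' requires missing upstream artifact(s): %s",
                 stage, paste(basename(missing), collapse = ", ")),
         call. = FALSE)
  }
}

load_graphs <- function(config) {
  list(tel = if (is.null(config$tel_pathway)) tmm_pathway("TEL") else
         load_pathway(config$tel_pathway),
       alt = if (is.null(config$alt_pathway)) tmm_pathway("ALT") else
         load_pathway(config$alt_pathway))
}

#' Run the TMM analysis pipeline
#'
#' Executes the requested stages in canonical order, writing each stage's
#' TSV/JSON artifacts plus a manifest (config hash, seed, input/output
#' checksums, package version) under `config$out_dir`.  All stages are
#' deterministic given the config, so a rerun with unchanged inputs
#' reproduces the artifacts byte for byte; stages can be rerun individually
#' as long as their upstream artifacts exist.
#'
#' Stages: `simulate` (synthetic cohort), `psf` (fold changes and PSF
#' activities for both pathways), `phenotype` (segmented thresholds and the
#' five-phenotype calls), `msi` (Kruskal-Wallis and Dunn comparisons of
#' pathway and branch activity across MSI groups), `survival` (KM, pairwise
#' log-rank and Cox hazard ratios for OS and PFS), `diffexp` (per-cancer
#' phenotype-versus-reference DE and cross-cancer recurrence tallies),
#' `enrich` (GMT over-representation of recurrent genes; needs `config$gmt`).
#'
#' @param config A [pipeline_config()].
#' @param stages Subset of the stage names, any order.
#' @return Invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- list()
  for (stage in PIPELINE_STAGES[PIPELINE_STAGES %in% stages]) {
    t0 <- proc.time()[["elapsed"]]
    written[[stage]] <- switch(stage,
      simulate = stage_simulate(config),
      psf = stage_psf(config),
      phenotype = stage_phenotype(config),
      msi = stage_msi(config),
      survival = stage_survival(config),
      diffexp = stage_diffexp(config),
      enrich = stage_enrich(config))
    message(sprintf("[tmmflow] stage %-9s done in %.1fs (%d artifact(s))",
                    stage, proc.time()[["elapsed"]] - t0,
                    length(written[[stage]])))
  }
  invisible(written)
}

stage_simulate <- function(config) {
  graphs <- load_graphs(config)
  sim <- generate_cohort(config$synthetic, tel_graph = graphs$tel,
                         alt_graph = graphs$alt)
  outs <- c(artifact(config, "counts.tsv"), artifact(config, "cohort.tsv"),
            artifact(config, "truth.tsv"))
  write_matrix_tsv(sim$counts, outs[1])
  utils::write.table(sim$cohort, outs[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth, outs[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_manifest(config, "simulate", character(0), outs)
  outs
}

counts_path <- function(config) {
  if (!is.null(config$counts)) config$counts else artifact(config, "counts.tsv")
}

cohort_path <- function(config) {
  if (!is.null(config$cohort)) config$cohort else artifact(config, "cohort.tsv")
}

stage_psf <- function(config) {
  inp <- counts_path(config)
  require_artifacts(config, "psf", inp)
  counts <- collapse_duplicates(read_counts_tsv(inp))
  fc <- to_fold_change(counts, pseudocount = config$pseudocount)
  graphs <- load_graphs(config)
  outs <- c(artifact(config, "psf_tel.tsv"), artifact(config, "psf_alt.tsv"))
  utils::write.table(psf_matrix(graphs$tel, fc), outs[1], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(psf_matrix(graphs$alt, fc), outs[2], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_manifest(config, "psf", inp, outs)
  outs
}

read_psf <- function(config) {
  list(tel = utils::read.delim(artifact(config, "psf_tel.tsv"),
                               check.names = FALSE),
       alt = utils::read.delim(artifact(config, "psf_alt.tsv"),
                               check.names = FALSE))
}

stage_phenotype <- function(config) {
  inp <- c(artifact(config, "psf_tel.tsv"), artifact(config, "psf_alt.tsv"))
  require_artifacts(config, "phenotype", inp)
  psf <- read_psf(config)
  strata <- NULL
  if (config$scope == "per_stratum") {
    require_artifacts(config, "phenotype", cohort_path(config))
    clin <- utils::read.delim(cohort_path(config))
    strata <- clin$cancer_type[match(psf$alt$sample, clin$sample)]
  }
  ph <- phenotype_cohort(psf$alt$log10_activity, psf$tel$log10_activity,
                         sample = psf$alt$sample, scope = config$scope,
                         strata = strata)
  outs <- c(artifact(config, "phenotypes.tsv"),
            artifact(config, "thresholds.json"))
  calls <- ph$calls
  names(calls)[names(calls) == "alt_value"] <- "alt_log10_psf"
  names(calls)[names(calls) == "tel_value"] <- "tel_log10_psf"
  utils::write.table(calls, outs[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  thr <- function(m) m[c("axis", "scale", "t_low", "t_high", "breakpoints",
                         "rss", "n")]
  models <- if (config$scope == "pooled") {
    list(ALT = thr(ph$alt_model), TEL = thr(ph$tel_model))
  } else {
    list(ALT = lapply(ph$alt_model, thr), TEL = lapply(ph$tel_model, thr))
  }
  jsonlite::write_json(models, outs[2], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  write_manifest(config, "phenotype", inp, outs)
  outs
}

stage_msi <- function(config) {
  inp <- c(artifact(config, "psf_tel.tsv"), artifact(config, "psf_alt.tsv"),
           cohort_path(config))
  require_artifacts(config, "msi", inp)
  psf <- read_psf(config)
  clin <- utils::read.delim(cohort_path(config))
  msi <- clin$msi[match(psf$alt$sample, clin$sample)]
  ok <- !is.na(msi)
  rows <- list(); dunn_rows <- list()
  for (pw in c("TEL", "ALT")) {
    tab <- if (pw == "TEL") psf$tel else psf$alt
    branch_cols <- setdiff(names(tab),
                           c("sample", "pathway", "activity", "log10_activity"))
    for (col in c("activity", branch_cols)) {
      grp <- split(tab[[col]][ok], msi[ok])
      grp <- grp[lengths(grp) > 0]
      if (length(grp) < 2) next
      kw <- kruskal_wallis(grp)
      rows[[length(rows) + 1L]] <- data.frame(
        pathway = pw, level = if (col == "activity") "pathway" else col,
        H = kw$H, p = kw$p, stringsAsFactors = FALSE)
      dt <- dunn_test(grp)
      dt <- cbind(pathway = pw,
                  level = if (col == "activity") "pathway" else col, dt)
      dunn_rows[[length(dunn_rows) + 1L]] <- dt
    }
  }
  outs <- c(artifact(config, "msi_kruskal.tsv"), artifact(config, "msi_dunn.tsv"))
  utils::write.table(do.call(rbind, rows), outs[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(do.call(rbind, dunn_rows), outs[2], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_manifest(config, "msi", inp, outs)
  outs
}

stage_survival <- function(config) {
  inp <- c(artifact(config, "phenotypes.tsv"), cohort_path(config))
  require_artifacts(config, "survival", inp)
  calls <- utils::read.delim(artifact(config, "phenotypes.tsv"))
  clin <- utils::read.delim(cohort_path(config))
  m <- merge(calls[, c("sample", "phenotype")], clin, by = "sample")
  outs <- character(0)
  global <- list()
  for (ep in c("os", "pfs")) {
    tm <- m[[paste0(ep, "_time")]]; ev <- m[[paste0(ep, "_event")]]
    lr <- logrank(tm, ev, m$phenotype, pairwise = TRUE)
    global[[ep]] <- list(chisq = lr$chisq, df = lr$df, p = lr$p)
    f_pw <- artifact(config, paste0("survival_", ep, "_pairwise_logrank.tsv"))
    utils::write.table(lr$pairwise, f_pw, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    hr <- cox_hr(tm, ev, m$phenotype, reference = "ALT_low_TEL_low")
    f_hr <- artifact(config, paste0("survival_", ep, "_cox.tsv"))
    utils::write.table(hr, f_hr, sep = "\t", quote = FALSE, row.names = FALSE)
    km <- do.call(rbind, lapply(split(seq_len(nrow(m)), m$phenotype),
      function(idx) {
        if (length(idx) == 0) return(NULL)
        cbind(phenotype = m$phenotype[idx[1]],
              km_estimate(tm[idx], ev[idx]))
      }))
    f_km <- artifact(config, paste0("survival_", ep, "_km.tsv"))
    utils::write.table(km, f_km, sep = "\t", quote = FALSE, row.names = FALSE)
    outs <- c(outs, f_pw, f_hr, f_km)
  }
  f_gl <- artifact(config, "survival_logrank.json")
  jsonlite::write_json(global, f_gl, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  outs <- c(outs, f_gl)
  write_manifest(config, "survival", inp, outs)
  outs
}

stage_diffexp <- function(config) {
  inp <- c(counts_path(config), artifact(config, "phenotypes.tsv"),
           cohort_path(config))
  require_artifacts(config, "diffexp", inp)
  counts <- collapse_duplicates(read_counts_tsv(counts_path(config)))
  calls <- utils::read.delim(artifact(config, "phenotypes.tsv"))
  clin <- utils::read.delim(cohort_path(config))
  labels <- calls$phenotype[match(colnames(counts), calls$sample)]
  cancer <- clin$cancer_type[match(colnames(counts), clin$sample)]
  targets <- setdiff(TMM_PHENOTYPES, "ALT_low_TEL_low")
  outs <- character(0)
  for (tg in targets) {
    per_cancer <- list()
    for (ct in unique(cancer[!is.na(cancer)])) {
      idx <- which(cancer == ct)
      lab <- labels[idx]
      if (sum(lab == tg, na.rm = TRUE) < 2 ||
          sum(lab == "ALT_low_TEL_low", na.rm = TRUE) < 2) next
      per_cancer[[ct]] <- differential_expression(
        counts[, idx, drop = FALSE], lab, target = tg,
        alpha = config$alpha)
    }
    if (length(per_cancer) == 0) next
    de_all <- do.call(rbind, Map(cbind, cancer_type = names(per_cancer),
                                 per_cancer))
    f_de <- artifact(config, paste0("de_", tg, ".tsv"))
    utils::write.table(de_all, f_de, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outs <- c(outs, f_de)
    for (dir in c("up", "down")) {
      tall <- recurrence_tally(per_cancer, direction = dir)
      f_t <- artifact(config, paste0("recurrence_", dir, "_", tg, ".tsv"))
      utils::write.table(tall, f_t, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outs <- c(outs, f_t)
    }
  }
  write_manifest(config, "diffexp", inp, outs)
  outs
}

stage_enrich <- function(config) {
  if (is.null(config$gmt)) {
    stop("stage 'enrich' requires a GMT file in the config", call. = FALSE)
  }
  counts_f <- counts_path(config)
  de_files <- Sys.glob(file.path(config$out_dir, "recurrence_up_*.tsv"))
  if (length(de_files) == 0) {
    stop("stage 'enrich' requires missing upstream artifact(s): ",
         "recurrence_up_*.tsv (run 'diffexp' first)", call. = FALSE)
  }
  require_artifacts(config, "enrich", counts_f)
  universe <- rownames(collapse_duplicates(read_counts_tsv(counts_f)))
  sets <- read_gmt(config$gmt)
  outs <- character(0)
  for (f in de_files) {
    tall <- utils::read.delim(f)
    de <- tall$gene[tall$n_cancer_types >= 2]
    if (length(de) == 0) de <- tall$gene[tall$in_top]
    ora <- ora_hypergeometric(de, sets, universe, q_cutoff = config$q_cutoff)
    f_out <- artifact(config, sub("^recurrence_up_", "ora_", basename(f)))
    utils::write.table(ora, f_out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outs <- c(outs, f_out)
  }
  write_manifest(config, "enrich", c(counts_f, de_files), outs)
  outs
}
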