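#' Phenotype-versus-reference differential expression
#'
#' Per gene, a Welch two-sample t-test on size-factor-normalized
#' `log2(count + 1)` values between the target phenotype and the reference
#' (`ALT_low_TEL_low` by default), with `log2fc = mean(target) -
#' mean(reference)` and BH adjustment across genes.  This is a deliberately
#' simple moderated-model-free engine with the same interface as a
#' negative-binomial fit, so a stricter engine can be swapped in.
#'
#' @param counts Gene x sample count matrix covering both groups.
#' @param labels Phenotype label per sample (length `ncol(counts)`).
#' @param target Phenotype to contrast against the reference.
#' @param reference Reference phenotype; default `"ALT_low_TEL_low"`.
#' @param alpha Significance level on the adjusted p-value.
#' @param lfc_floor Minimum `|log2fc|` for a non-`ns` direction call.
#' @return Data frame: `gene`, `log2fc`, `p`, `p_adjusted`, `direction`
#'   (`up`/`down`/`ns`).
#' @export
differential_expression <- function(counts, labels, target,
                                    reference = "ALT_low_TEL_low",
                                    alpha = 0.05, lfc_floor = 0) {
  stopifnot(ncol(counts) == length(labels))
  in_t <- labels == target
  in_r <- labels == reference
  if (sum(in_t) < 2 || sum(in_r) < 2) {
    stop("need at least 2 samples in both target and reference groups",
         call. = FALSE)
  }
  sub <- counts[, in_t | in_r, drop = FALSE]
  f <- size_factors(sub)
  x <- log2(sweep(sub, 2, f, "/") + 1)
  grp <- labels[in_t | in_r] == target
  x_t <- x[, grp, drop = FALSE]
  x_r <- x[, !grp, drop = FALSE]
  m_t <- rowMeans(x_t); m_r <- rowMeans(x_r)
  v_t <- apply(x_t, 1, stats::var); v_r <- apply(x_r, 1, stats::var)
  n_t <- ncol(x_t); n_r <- ncol(x_r)
  se2 <- v_t / n_t + v_r / n_r
  tstat <- (m_t - m_r) / sqrt(se2)
  df <- se2^2 / ((v_t / n_t)^2 / (n_t - 1) + (v_r / n_r)^2 / (n_r - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[!is.finite(p)] <- 1 # constant genes: no evidence either way
  padj <- bh_adjust(p)
  lfc <- m_t - m_r
  dir <- ifelse(padj < alpha & abs(lfc) >= lfc_floor,
                ifelse(lfc > 0, "up", "down"), "ns")
  data.frame(gene = rownames(counts), log2fc = lfc, p = p,
             p_adjusted = padj, direction = dir,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up procedure via [stats::p.adjust()], with input
#' validation: p-values must lie in (0, 1].
#'
#' @param pvalues Numeric vector.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Cross-cancer recurrence tally of differentially expressed genes
#'
#' Counts, for every gene, in how many cancer types it was called
#' significant in the stated direction, and flags the top-k most recurrent
#' genes with ties kept (the basis of "upregulated in N cancer types"
#' summaries).
#'
#' @param per_cancer_de Named list (cancer type -> DE result data frame from
#'   [differential_expression()]).
#' @param direction `"up"` or `"down"`.
#' @param top_k Size of the flagged head of the table (ties at the boundary
#'   kept).
#' @return Data frame sorted by decreasing count: `gene`, `n_cancer_types`,
#'   `in_top`.
#' @export
recurrence_tally <- function(per_cancer_de, direction = c("up", "down"),
                             top_k = 50) {
  direction <- match.arg(direction)
  if (length(per_cancer_de) == 0) {
    return(data.frame(gene = character(0), n_cancer_types = integer(0),
                      in_top = logical(0), stringsAsFactors = FALSE))
  }
  hits <- lapply(per_cancer_de, function(de) {
    unique(de$gene[de$direction == direction])
  })
  tab <- table(unlist(hits, use.names = FALSE))
  if (length(tab) == 0) {
    return(data.frame(gene = character(0), n_cancer_types = integer(0),
                      in_top = logical(0), stringsAsFactors = FALSE))
  }
  out <- data.frame(gene = names(tab), n_cancer_types = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_cancer_types, out$gene), ]
  cutoff <- if (nrow(out) <= top_k) 0L else out$n_cancer_types[top_k]
  out$in_top <- out$n_cancer_types >= max(cutoff, 1L)
  rownames(out) <- NULL
  out
}

#' Read a GMT gene-set collection
#'
#' Standard tab-separated format: set name, description, then gene symbols.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors (upper-cased symbols).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3) stop("GMT line with fewer than 3 fields", call. = FALSE)
    toupper(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1)
  sets
}

#' Hypergeometric over-representation of gene sets
#'
#' Database-free replacement for GO enrichment: for each set, the upper-tail
#' hypergeometric probability of observing at least the seen overlap between
#' the differentially expressed genes and the set, within the universe.
#' Sets and DE genes are intersected with the universe first; q-values are
#' BH across sets.
#'
#' @param de_genes Character vector of significant genes.
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Character vector of assayable genes (e.g. rownames of the
#'   count matrix).
#' @param q_cutoff Significance cutoff on the q-value.
#' @return Data frame: `set`, `set_size`, `overlap`, `p`, `q`, `significant`.
#' @export
ora_hypergeometric <- function(de_genes, sets, universe, q_cutoff = 0.05) {
  universe <- unique(toupper(universe))
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  de <- intersect(unique(toupper(de_genes)), universe)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(toupper(sets[[nm]])), universe)
    k <- length(intersect(s, de))
    # P[X >= k], X ~ Hypergeom(white = |set|, black = |universe| - |set|,
    # drawn = |de|)
    p <- stats::phyper(k - 1, length(s), length(universe) - length(s),
                       length(de), lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < q_cutoff
  out
}
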