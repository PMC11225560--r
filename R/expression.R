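#' Read a gene x sample count matrix from TSV
#'
#' First column holds gene symbols (upper-cased on load), the header holds
#' sample ids.  Duplicate symbols are kept; collapse them explicitly with
#' [collapse_duplicates()].
#'
#' @param path Path to a TSV file.
#' @return Integer-like numeric matrix, genes in rows.
#' @export
read_counts_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- toupper(tab[[1]])
  if (any(m < 0)) stop("negative counts in ", path, call. = FALSE)
  m
}

#' Write a numeric gene x sample matrix as TSV
#'
#' @param m Matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a single-cell count matrix from MTX triplet format
#'
#' Standard 10x-style layout: a MatrixMarket sparse matrix with features in
#' rows and barcodes in columns, plus `features.tsv` (gene symbol in the
#' given column) and `barcodes.tsv`.  Returns a dense gene x cell matrix so
#' the bulk fold-change path applies unchanged; intended for pathway-sized
#' analyses, not genome-wide single-cell work.
#'
#' @param mtx,features,barcodes File paths.
#' @param symbol_column Column of `features` holding the gene symbol.
#' @return Numeric matrix, genes x cells.
#' @export
read_counts_mtx <- function(mtx, features, barcodes, symbol_column = 2L) {
  m <- as.matrix(Matrix::readMM(mtx))
  feat <- utils::read.delim(features, header = FALSE, stringsAsFactors = FALSE)
  bc <- utils::read.delim(barcodes, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(feat) != nrow(m) || nrow(bc) != ncol(m)) {
    stop("features/barcodes dimensions do not match the MTX matrix", call. = FALSE)
  }
  symbol_column <- min(symbol_column, ncol(feat))
  rownames(m) <- toupper(feat[[symbol_column]])
  colnames(m) <- bc[[1]]
  m
}

#' Collapse duplicate gene symbols by summing counts
#'
#' Rows sharing a symbol are summed; the order of first occurrence is
#' preserved.
#'
#' @param counts Gene x sample count matrix.
#' @return Matrix with unique rownames.
#' @export
collapse_duplicates <- function(counts) {
  if (!anyDuplicated(rownames(counts))) return(counts)
  keys <- factor(rownames(counts), levels = unique(rownames(counts)))
  out <- rowsum(counts, keys, reorder = FALSE)
  rownames(out) <- levels(keys)
  out
}

#' Median-of-ratios library size factors
#'
#' Per-gene reference = geometric mean of counts over samples, restricted to
#' genes with all-positive counts; each sample's factor is the median over
#' those genes of count/reference.  Factors are rescaled to have geometric
#' mean 1 so the cohort's overall scale is untouched.
#'
#' @param counts Gene x sample count matrix, at least two samples.
#' @return Positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  if (ncol(counts) < 2) stop("need at least two samples", call. = FALSE)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop("no gene has all-positive counts; add a pseudocount before ",
         "computing size factors", call. = FALSE)
  }
  logc <- log(counts[pos, , drop = FALSE])
  ref <- exp(rowMeans(logc))
  f <- apply(counts[pos, , drop = FALSE] / ref, 2, stats::median)
  f <- f / exp(mean(log(f)))
  f
}

#' Convert counts to a fold-change matrix
#'
#' The PSF input: counts are divided by their sample's size factor,
#' log2-transformed with a pseudocount, centered per gene on the gene's mean
#' over all samples (the cohort is the reference), and de-logged.  Every
#' gene's fold changes thus have geometric mean 1 across samples.
#'
#' @param counts Gene x sample count matrix.
#' @param factors Size factors from [size_factors()]; computed if `NULL`.
#' @param pseudocount Added before the log; must be positive when zeros are
#'   present.  Default 1.
#' @return Positive matrix of fold changes, same dimnames as `counts`.
#' @export
to_fold_change <- function(counts, factors = NULL, pseudocount = 1) {
  if (is.null(factors)) factors <- size_factors(counts)
  if (length(factors) != ncol(counts) || any(factors <= 0)) {
    stop("factors must be positive, one per sample", call. = FALSE)
  }
  if (pseudocount <= 0 && any(counts == 0)) {
    stop("non-positive pseudocount with zero counts present", call. = FALSE)
  }
  x <- log2(sweep(counts, 2, factors, "/") + pseudocount)
  x <- x - rowMeans(x)
  2^x
}
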