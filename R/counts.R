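#' Read / write a gene-by-sample count matrix
#'
#' Counts are stored as TSV with gene ids in the first column (`gene_id`)
#' and one column per sample. `read_counts` validates the format: unique
#' gene and sample ids, non-negative integer entries.
#'
#' @param path File path.
#' @return `read_counts` returns an integer matrix with gene ids as
#'   rownames and sample ids as colnames; `write_counts` returns `path`
#'   invisibly. Round trip is an identity.
#' @export
read_counts <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("count file must have a gene_id column and at least one sample")
  gene_ids <- as.character(d[[1]])
  if (anyDuplicated(gene_ids)) {
    stop("format error: duplicated gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  samples <- colnames(d)[-1]
  if (anyDuplicated(samples)) {
    stop("format error: duplicated sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  x <- as.matrix(d[, -1, drop = FALSE])
  bad <- which(is.na(x) | x < 0 | x != round(x), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "format error: negative or non-integer count at gene '%s', sample '%s'",
      gene_ids[bad[1, 1]], samples[bad[1, 2]]))
  }
  storage.mode(x) <- "integer"
  rownames(x) <- gene_ids
  x
}

#' @param counts Integer matrix, genes x samples, with dimnames.
#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)), !is.null(colnames(counts)))
  d <- data.frame(gene_id = rownames(counts), counts,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

lib_sizes <- function(counts, lib.size = NULL) {
  ls <- if (is.null(lib.size)) colSums(counts) else lib.size
  if (length(ls) != ncol(counts)) stop("library sizes must match the sample count")
  if (any(ls <= 0)) {
    stop("zero or negative library size for sample(s): ",
         paste(colnames(counts)[ls <= 0], collapse = ", "))
  }
  ls
}

#' Counts per million
#'
#' CPM = count / (library size x normalization factor) x 1e6. Without
#' factors every column sums to exactly 1e6.
#'
#' @param counts Gene x sample count matrix.
#' @param factors Optional per-sample normalization factors from
#'   [tmm_factors()]; must have geometric mean 1.
#' @param lib.size Optional per-sample library sizes (default: column sums).
#' @return Numeric matrix of CPM values.
#' @export
cpm <- function(counts, factors = NULL, lib.size = NULL) {
  ls <- lib_sizes(counts, lib.size)
  if (!is.null(factors)) {
    check_norm_factors(factors, ncol(counts))
    ls <- ls * factors
  }
  t(t(counts) / ls) * 1e6
}

check_norm_factors <- function(factors, n_samples) {
  if (length(factors) != n_samples) {
    stop("normalization factors must match the sample count")
  }
  if (any(factors <= 0)) stop("normalization factors must be positive")
  if (abs(mean(log(factors))) > 1e-9) {
    stop("normalization factors must have geometric mean 1")
  }
  invisible(factors)
}

#' Filter genes with low expression
#'
#' Keeps genes whose CPM is at or above `cpm_threshold` in at least
#' `min_samples` samples; the sample set is unchanged. Default
#' `min_samples` is the size of the smallest genetic-group cell of the
#' study design (3), so that a gene expressed in only one full cell
#' survives. Idempotent.
#'
#' @param counts Gene x sample count matrix.
#' @param cpm_threshold CPM below which a gene is considered unexpressed
#'   in a sample (default 0.5).
#' @param min_samples Minimum number of samples at or above the threshold.
#' @param lib.size Optional library sizes; defaults to column sums of the
#'   unfiltered matrix.
#' @return The filtered count matrix.
#' @export
filter_low_expression <- function(counts, cpm_threshold = 0.5, min_samples = 3,
                                  lib.size = NULL) {
  if (cpm_threshold < 0) stop("'cpm_threshold' must be >= 0")
  if (min_samples > ncol(counts)) {
    stop("'min_samples' (", min_samples, ") exceeds the sample count (",
         ncol(counts), ")")
  }
  x <- cpm(counts, lib.size = lib.size)
  keep <- rowSums(x >= cpm_threshold) >= min_samples
  counts[keep, , drop = FALSE]
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scale factors relative to a reference sample,
#' computed by edgeR: per sample, the inverse-variance-weighted mean of
#' log2 expression ratios (M-values) against the reference after trimming
#' the most extreme 30 percent of M-values and 5 percent of average
#' abundances, rescaled so the factors have geometric mean 1. The
#' reference is the sample whose upper quartile of scaled counts is
#' closest to the mean upper quartile.
#'
#' @param counts Gene x sample count matrix (at least 2 samples).
#' @param lib.size Optional library sizes.
#' @param m_trim,a_trim Trim fractions for M-values and average abundance.
#' @return Named numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, lib.size = NULL, m_trim = 0.30, a_trim = 0.05) {
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  ls <- lib_sizes(counts, lib.size)
  shared <- crossprod(counts > 0)   # samples sharing >= 1 expressed gene
  if (any(shared == 0)) {
    bad <- which(shared == 0, arr.ind = TRUE)[1, ]
    stop("samples '", colnames(counts)[bad[1]], "' and '",
         colnames(counts)[bad[2]], "' share no expressed gene")
  }
  f <- edgeR::calcNormFactors(counts, lib.size = ls, method = "TMM",
                              logratioTrim = m_trim, sumTrim = a_trim)
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Log2 counts per million
#'
#' log2(CPM + prior_count): finite for zero counts and exactly invariant
#' to doubling a sample's counts and library size together.
#'
#' @inheritParams cpm
#' @param prior_count Positive offset added to CPM before the log
#'   (default 0.5).
#' @return Numeric matrix of log2(CPM + prior_count) values.
#' @export
log_cpm <- function(counts, factors = NULL, prior_count = 0.5, lib.size = NULL) {
  if (prior_count <= 0) stop("'prior_count' must be > 0")
  log2(cpm(counts, factors = factors, lib.size = lib.size) + prior_count)
}
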