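#' Remove batch effects from a log-expression matrix
#'
#' Per-gene linear removal of batch means after adjusting for the design
#' factors that must be preserved (by default tissue, genetic group and
#' sex). On balanced designs preserved group contrasts are unchanged.
#' Batch components that are confounded with (linearly dependent on) the
#' preserved factors trigger a warning and are left untouched.
#'
#' @param logmat Gene x sample log2 CPM matrix.
#' @param design Design table matching `colnames(logmat)`.
#' @param preserve Design columns whose group structure must be preserved.
#' @return The batch-centered matrix.
#' @export
batch_center <- function(logmat, design,
                         preserve = c("tissue", "group", "sex")) {
  design <- design[match(colnames(logmat), design$sample_id), , drop = FALSE]
  if (anyNA(design$sample_id)) stop("every sample needs a design row")
  if (anyNA(design$batch)) stop("every sample needs a batch label")
  batch <- factor(design$batch)
  if (nlevels(batch) < 2) return(logmat)
  preserve <- intersect(preserve, names(design))
  keep <- vapply(preserve, function(f) length(unique(design[[f]])) > 1, logical(1))
  covariates <- preserve[keep]
  X <- if (length(covariates)) {
    fac <- as.data.frame(lapply(design[covariates], factor))
    stats::model.matrix(stats::reformulate(covariates), data = fac)
  } else {
    matrix(1, ncol(logmat), 1)
  }
  # sum-to-zero batch coding, as limma uses, so the grand level is kept
  B <- stats::model.matrix(~batch, contrasts.arg = list(batch = "contr.sum"))
  B <- B[, -1, drop = FALSE]
  aliased <- vapply(seq_len(ncol(B)), function(j) {
    qr(cbind(X, B[, j]))$rank == qr(X)$rank
  }, logical(1))
  if (any(aliased)) {
    warning("batch is confounded with preserved design factors; ",
            "aliased batch components left unadjusted")
    B <- B[, !aliased, drop = FALSE]
    if (ncol(B) == 0) return(logmat)
  }
  limma::removeBatchEffect(logmat, covariates = B, design = X)
}

#' Mean log2 CPM per genetic group within tissue
#'
#' @param logmat Gene x sample log2 CPM matrix.
#' @param design Design table matching `colnames(logmat)`.
#' @return A data.frame with one row per (gene, tissue): `gene_id`,
#'   `tissue`, and `m1`..`m4`, the mean log2 CPM of genetic groups 1-4.
#'   Errors if any (tissue, group) cell has no samples.
#' @export
group_means <- function(logmat, design) {
  design <- design[match(colnames(logmat), design$sample_id), , drop = FALSE]
  if (anyNA(design$sample_id)) stop("every sample needs a design row")
  tissues <- unique(design$tissue)
  groups <- sort(unique(design$group))
  out <- vector("list", length(tissues))
  for (ti in seq_along(tissues)) {
    t <- tissues[ti]
    cols <- lapply(groups, function(g) which(design$tissue == t & design$group == g))
    empty <- groups[lengths(cols) == 0]
    if (length(empty)) {
      stop("no samples for tissue '", t, "', group(s) ",
           paste(empty, collapse = ", "))
    }
    mm <- vapply(cols, function(j) rowMeans(logmat[, j, drop = FALSE]),
                 numeric(nrow(logmat)))
    colnames(mm) <- paste0("m", groups)
    out[[ti]] <- data.frame(gene_id = rownames(logmat), tissue = t, mm,
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Most abundant genes per tissue and tissue-specific high expressers
#'
#' Ranks genes within each tissue by mean log2 CPM (ties broken by gene
#' id) and reports the top `n`, plus the genes exceeding
#' `tissue_specific_cutoff` in exactly one tissue.
#'
#' @param logmat Gene x sample log2 CPM matrix.
#' @param design Design table matching `colnames(logmat)`.
#' @param n Number of top genes per tissue.
#' @param tissue_specific_cutoff Mean log2 CPM above which a gene counts
#'   as highly expressed in a tissue (default 10).
#' @return A list with `top` (data.frame: `tissue`, `rank`, `gene_id`,
#'   `mean_log2_cpm`) and `tissue_specific_high` (data.frame: `gene_id`,
#'   `tissue` where it alone exceeds the cutoff).
#' @export
top_expressed <- function(logmat, design, n = 20, tissue_specific_cutoff = 10) {
  if (n < 1) stop("'n' must be >= 1")
  design <- design[match(colnames(logmat), design$sample_id), , drop = FALSE]
  tissues <- unique(design$tissue)
  means <- vapply(tissues, function(t) {
    rowMeans(logmat[, design$tissue == t, drop = FALSE])
  }, numeric(nrow(logmat)))
  colnames(means) <- tissues
  top <- do.call(rbind, lapply(tissues, function(t) {
    ord <- order(-means[, t], rownames(logmat))
    k <- min(n, nrow(logmat))
    data.frame(tissue = t, rank = seq_len(k),
               gene_id = rownames(logmat)[ord[seq_len(k)]],
               mean_log2_cpm = means[ord[seq_len(k)], t],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  high <- means > tissue_specific_cutoff
  once <- which(rowSums(high) == 1)
  ts <- data.frame(
    gene_id = rownames(logmat)[once],
    tissue = tissues[max.col(high[once, , drop = FALSE], ties.method = "first")],
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(top = top, tissue_specific_high = ts[order(ts$gene_id), , drop = FALSE])
}
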