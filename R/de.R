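#' Two-group differential expression on log2 CPM
#'
#' Per-gene Welch two-sample t-test between two genetic groups within one
#' tissue, pooling sexes, with Benjamini-Hochberg adjustment across all
#' tested genes. The Welch test on log2 CPM is this package's documented
#' stand-in for moderated linear-model pipelines; the DE stage is a single
#' pluggable interface.
#'
#' @param logmat Gene x sample log2 CPM matrix.
#' @param design Design table matching `colnames(logmat)`.
#' @param tissue Tissue to test within.
#' @param groupA,groupB Genetic group codes to contrast; the log2 fold
#'   change is groupA minus groupB.
#' @return A data.frame with one row per gene: `gene_id`, `tissue`,
#'   `contrast`, `log2_fold_change`, `t_statistic`, `df`, `p_value`,
#'   `q_value`, `mean_expression`.
#' @export
de_test <- function(logmat, design, tissue, groupA, groupB) {
  design <- design[match(colnames(logmat), design$sample_id), , drop = FALSE]
  ia <- which(design$tissue == tissue & design$group == groupA)
  ib <- which(design$tissue == tissue & design$group == groupB)
  if (length(ia) < 2 || length(ib) < 2) {
    stop("need at least 2 samples per group (got ", length(ia), " and ",
         length(ib), " for tissue '", tissue, "')")
  }
  xa <- logmat[, ia, drop = FALSE]
  xb <- logmat[, ib, drop = FALSE]
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  # zero-variance genes (identical values in both groups): no evidence
  zero <- se2 == 0
  tstat[zero] <- 0
  df[zero] <- na + nb - 2
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  data.frame(
    gene_id = rownames(logmat),
    tissue = tissue,
    contrast = paste0(groupA, "v", groupB),
    log2_fold_change = ma - mb,
    t_statistic = tstat,
    df = df,
    p_value = p,
    q_value = bh_adjust(p),
    mean_expression = (ma * na + mb * nb) / (na + nb),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: q_i is the minimum over ranks j >= rank(i) of
#' p_(j) * m / j, capped at 1.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Select differentially expressed genes
#'
#' Genes with q-value strictly below `fdr` and |log2 fold change| at or
#' above `min_abs_log2fc` (a fold-change filter of 2 corresponds to
#' `min_abs_log2fc = 1`).
#'
#' @param results A [de_test()] table from a single contrast.
#' @param fdr FDR threshold (strict, default 0.05).
#' @param min_abs_log2fc Minimum |log2 fold change| (non-strict, default 0).
#' @return Character vector of selected gene ids.
#' @export
deg_select <- function(results, fdr = 0.05, min_abs_log2fc = 0) {
  if (nrow(results) == 0) return(character(0))
  sel <- results$q_value < fdr & abs(results$log2_fold_change) >= min_abs_log2fc
  results$gene_id[sel]
}

#' Summarise DEG sets across tissues
#'
#' Computes every Venn region of the per-tissue DEG sets, the
#' all-tissue intersection, and the tissue-specific (exactly one tissue)
#' sets.
#'
#' @param deg_sets Named list of character vectors, one per tissue.
#' @return A list with `region_sizes` (named by membership pattern, e.g.
#'   `"brain&liver"`), `union_size`, `shared_all` (ids in every tissue)
#'   and `tissue_specific` (named list of ids unique to one tissue).
#' @export
degs_across_tissues <- function(deg_sets) {
  if (length(deg_sets) < 1) stop("need at least one tissue")
  stopifnot(!is.null(names(deg_sets)))
  tissues <- names(deg_sets)
  all_ids <- unique(unlist(deg_sets, use.names = FALSE))
  membership <- vapply(deg_sets, function(s) all_ids %in% s,
                       logical(length(all_ids)))
  if (length(all_ids) == 1) membership <- matrix(membership, nrow = 1)
  pattern <- apply(membership, 1, function(z) paste(tissues[z], collapse = "&"))
  region_sizes <- table(pattern)
  shared_all <- all_ids[rowSums(membership) == length(tissues)]
  specific <- lapply(seq_along(tissues), function(i) {
    sort(all_ids[membership[, i] & rowSums(membership) == 1])
  })
  names(specific) <- tissues
  list(
    region_sizes = c(region_sizes),
    union_size = length(all_ids),
    shared_all = sort(shared_all),
    tissue_specific = specific
  )
}

#' DEG counts for all pairwise group contrasts in one tissue
#'
#' Runs [de_test()] for each of the six pairs of the four genetic groups
#' and counts DEGs per contrast.
#'
#' @inheritParams de_test
#' @param fdr,min_abs_log2fc Selection thresholds passed to [deg_select()].
#' @return A symmetric 4 x 4 matrix of DEG counts (diagonal 0), rows and
#'   columns named by group code.
#' @export
pairwise_group_deg_counts <- function(logmat, design, tissue,
                                      fdr = 0.05, min_abs_log2fc = 0) {
  design_t <- design[match(colnames(logmat), design$sample_id), , drop = FALSE]
  present <- sort(unique(design_t$group[design_t$tissue == tissue]))
  missing <- setdiff(1:4, present)
  if (length(missing)) {
    stop("tissue '", tissue, "' is missing genetic group(s) ",
         paste(missing, collapse = ", "))
  }
  out <- matrix(0L, 4, 4, dimnames = list(1:4, 1:4))
  for (a in 1:3) {
    for (b in seq(a + 1, 4)) {
      res <- de_test(logmat, design, tissue, a, b)
      n <- length(deg_select(res, fdr = fdr, min_abs_log2fc = min_abs_log2fc))
      out[a, b] <- out[b, a] <- n
    }
  }
  out
}
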