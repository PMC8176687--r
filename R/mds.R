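#' Multidimensional-scaling coordinates for sample QC
#'
#' Computes pairwise between-sample distances as the root-mean-square of
#' the `top` largest absolute log2 fold changes for that pair ("leading
#' fold change", selected pairwise), then embeds the distance matrix by
#' classical (Torgerson) scaling. Coordinates are defined up to rotation
#' and reflection, so downstream comparisons should use distances, not
#' axes.
#'
#' @param logmat Gene x sample log2 CPM matrix.
#' @param k Number of dimensions (default 2).
#' @param top Number of most-different genes used per sample pair
#'   (default 500, capped at the gene count).
#' @return A samples x k coordinate matrix. If all samples are identical
#'   the coordinates are all zero, with a warning.
#' @export
mds_coordinates <- function(logmat, k = 2, top = 500) {
  n <- ncol(logmat)
  if (n < k + 1) stop("need at least k + 1 samples")
  top <- min(top, nrow(logmat))
  D <- matrix(0, n, n, dimnames = list(colnames(logmat), colnames(logmat)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      fc2 <- (logmat[, i] - logmat[, j])^2
      sel <- sort(fc2, decreasing = TRUE)[seq_len(top)]
      D[i, j] <- D[j, i] <- sqrt(mean(sel))
    }
  }
  if (all(D == 0)) {
    warning("all samples identical; MDS coordinates are degenerate")
    return(matrix(0, n, k, dimnames = list(colnames(logmat), paste0("dim", seq_len(k)))))
  }
  coord <- stats::cmdscale(stats::as.dist(D), k = k)
  if (ncol(coord) < k) {  # rank-deficient configurations pad with zeros
    coord <- cbind(coord, matrix(0, n, k - ncol(coord)))
  }
  dimnames(coord) <- list(colnames(logmat), paste0("dim", seq_len(k)))
  coord
}
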