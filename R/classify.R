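#' Classifier thresholds
#'
#' Thresholds of the diff-ratio inheritance classifier. The ratio of the
#' reciprocal-cross separation to the purebred separation
#' (diff2-3 / diff1-4) must exceed `theta_high` to call parental-driven
#' expression; individual ratios below `theta_low` mark a cross as sitting
#' at a purebred's level. `min_d14` guards against ratio blow-up when the
#' purebreds are barely separated.
#'
#' Two rule systems are available. `"consistent"` (default) rewrites the
#' published inequality sets as mutually exclusive regions of the relative
#' cross positions, adding an explicit additive band and
#' proximity-to-dominant-parent conditions; `"as_printed"` evaluates the
#' eight published inequality sets verbatim, in printed order, first match
#' wins (the duplicated final label is corrected to indicine
#' dominant-activation). The printed dominant rules admit additive genes
#' and the printed list defines no additive rule; `as_printed` exists for
#' auditability, not for routine use.
#'
#' @param theta_high Ratio above which diff2-3/diff1-4 indicates
#'   parental-driven expression (default 0.8).
#' @param theta_low Ratio below which a difference is considered
#'   negligible (default 0.2).
#' @param min_d14 Minimum purebred separation (log2 units) for
#'   classification; genes below it are `UNCLASSIFIED` (default 0.5).
#' @param mode `"consistent"` or `"as_printed"`.
#' @return A list of class `classifier_thresholds`.
#' @export
classifier_thresholds <- function(theta_high = 0.8, theta_low = 0.2,
                                  min_d14 = 0.5,
                                  mode = c("consistent", "as_printed")) {
  mode <- match.arg(mode)
  if (!(theta_low > 0 && theta_low < 0.5)) {
    stop("config error: need 0 < theta_low < 0.5")
  }
  if (!(theta_high >= 0.5 && theta_high <= 1)) {
    stop("config error: need 0.5 <= theta_high <= 1")
  }
  if (min_d14 < 0) stop("config error: min_d14 must be >= 0")
  structure(list(theta_high = theta_high, theta_low = theta_low,
                 min_d14 = min_d14, mode = mode),
            class = "classifier_thresholds")
}

#' Pairwise group differences and diff ratios
#'
#' From the four group mean log2 expression values m1..m4 (groups 1 =
#' BtxBt, 2 = BixBt, 3 = BtxBi, 4 = BixBi) computes the six pairwise
#' absolute differences diff1-2 ... diff3-4, the five ratios of each
#' remaining difference to the purebred difference diff1-4, and the signed
#' relative positions of the two crosses on the purebred axis,
#' rel_g = (m_g - m4) / (m1 - m4). Ratios and relative positions are `NA`
#' when the purebred separation is below `min_d14`.
#'
#' @param m Numeric vector of length 4 (`m1`..`m4`), or a matrix /
#'   data.frame with four such columns (one row per gene).
#' @param min_d14 Minimum purebred separation for ratios to be defined.
#' @return A data.frame with columns `d12`, `d13`, `d14`, `d23`, `d24`,
#'   `d34`, `r12`, `r13`, `r23`, `r24`, `r34`, `rel2`, `rel3`,
#'   `signed_d14`.
#' @examples
#' pairwise_diffs(c(10, 9.85, 7.15, 7))$r23   # 0.9
#' @export
pairwise_diffs <- function(m, min_d14 = 0) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  m <- as.matrix(m)
  if (ncol(m) != 4) stop("'m' must have four group means m1..m4")
  if (any(!is.finite(m))) stop("group means must be finite")
  m1 <- m[, 1]; m2 <- m[, 2]; m3 <- m[, 3]; m4 <- m[, 4]
  d <- data.frame(
    d12 = abs(m1 - m2), d13 = abs(m1 - m3), d14 = abs(m1 - m4),
    d23 = abs(m2 - m3), d24 = abs(m2 - m4), d34 = abs(m3 - m4)
  )
  ok <- d$d14 >= min_d14 & d$d14 > 0
  denom <- ifelse(ok, d$d14, NA_real_)
  d$r12 <- d$d12 / denom
  d$r13 <- d$d13 / denom
  d$r23 <- d$d23 / denom
  d$r24 <- d$d24 / denom
  d$r34 <- d$d34 / denom
  d$rel2 <- (m2 - m4) / ifelse(ok, m1 - m4, NA_real_)
  d$rel3 <- (m3 - m4) / ifelse(ok, m1 - m4, NA_real_)
  d$signed_d14 <- m1 - m4
  d
}

# classify from the relative cross positions rel2, rel3 and the sign of
# m1 - m4; the workhorse behind both classify_gene and the complex-gene
# rejection sampler. `s` is sign(m1 - m4).
classify_relpos <- function(rel2, rel3, s, th) {
  hi <- th$theta_high
  lo <- th$theta_low
  r23 <- abs(rel2 - rel3)
  taurine_high <- s > 0
  if (th$mode == "consistent") {
    if (r23 > hi && rel2 > 1 - lo && rel3 < lo) {
      return(if (taurine_high) "MATERNAL_TAURINE" else "MATERNAL_INDICINE")
    }
    if (r23 > hi && rel3 > 1 - lo && rel2 < lo) {
      return(if (taurine_high) "PATERNAL_TAURINE" else "PATERNAL_INDICINE")
    }
    if (r23 < lo && rel2 > 1 - lo && rel3 > 1 - lo) {
      return(if (taurine_high) "TAURINE_DOMINANT_ACTIVATION"
             else "TAURINE_DOMINANT_INHIBITION")
    }
    if (r23 < lo && rel2 < lo && rel3 < lo) {
      return(if (!taurine_high) "INDICINE_DOMINANT_ACTIVATION"
             else "INDICINE_DOMINANT_INHIBITION")
    }
    if (r23 < lo &&
        rel2 >= lo && rel2 <= 1 - lo &&
        rel3 >= lo && rel3 <= 1 - lo) {
      return("ADDITIVE")
    }
    return("COMPLEX")
  }
  # as_printed: the published inequality sets, evaluated in printed order,
  # first match wins. In relative coordinates the printed ratios are
  # diff1-2/diff1-4 = |1 - rel2|, diff3-4/diff1-4 = |rel3|,
  # diff1-3/diff1-4 = |1 - rel3|, diff2-4/diff1-4 = |rel2|.
  r12 <- abs(1 - rel2); r34 <- abs(rel3)
  r13 <- abs(1 - rel3); r24 <- abs(rel2)
  if (r23 > hi && r12 < lo && r34 < lo && taurine_high) return("MATERNAL_TAURINE")
  if (r23 > hi && r12 < lo && r34 < lo && !taurine_high) return("MATERNAL_INDICINE")
  if (r23 > hi && r13 < lo && r24 < lo && taurine_high) return("PATERNAL_TAURINE")
  if (r23 > hi && r13 < lo && r24 < lo && !taurine_high) return("PATERNAL_INDICINE")
  if (r23 < lo && r24 < hi && r34 < hi && !taurine_high) return("TAURINE_DOMINANT_INHIBITION")
  if (r23 < lo && r24 < hi && r34 < hi && taurine_high) return("TAURINE_DOMINANT_ACTIVATION")
  if (r23 < lo && r12 < hi && r13 < hi && taurine_high) return("INDICINE_DOMINANT_INHIBITION")
  if (r23 < lo && r12 < hi && r13 < hi && !taurine_high) return("INDICINE_DOMINANT_ACTIVATION")
  "COMPLEX"
}

#' Classify one gene's inheritance mode
#'
#' Applies the diff-ratio rule system to one gene's pairwise differences.
#' The category is a pure function of the diff-ratio set, the sign of the
#' purebred difference m1 - m4, and the thresholds.
#'
#' @param ratios One-row data.frame from [pairwise_diffs()].
#' @param signed_d Signed purebred difference m1 - m4 (defaults to the
#'   `signed_d14` column of `ratios`).
#' @param thresholds A [classifier_thresholds()] object.
#' @return A single category string (see [inheritance_categories()]).
#' @examples
#' d <- pairwise_diffs(c(10, 9.85, 7.15, 7))
#' classify_gene(d)   # parental-driven: "MATERNAL_TAURINE"
#' @export
classify_gene <- function(ratios, signed_d = ratios$signed_d14,
                          thresholds = classifier_thresholds()) {
  stopifnot(inherits(thresholds, "classifier_thresholds"))
  if (nrow(ratios) != 1) stop("'ratios' must be a single row; see classify_table()")
  if (ratios$d14 < thresholds$min_d14 || ratios$d14 == 0 ||
      is.na(ratios$rel2) || is.na(ratios$rel3)) {
    return("UNCLASSIFIED")
  }
  classify_relpos(ratios$rel2, ratios$rel3, sign(signed_d), thresholds)
}

#' Classify a table of group-mean profiles
#'
#' Runs the inheritance classifier over every (gene, tissue) profile whose
#' gene is in the supplied set of purebred differentially expressed genes
#' (the classifier is only meaningful for genes whose purebreds are
#' separated).
#'
#' @param profiles A group-mean profile table from [group_means()]:
#'   columns `gene_id`, `tissue`, `m1`..`m4`.
#' @param deg_set Character vector of gene ids (typically purebred 1-vs-4
#'   DEGs). May be a named list of per-tissue id vectors, in which case
#'   each tissue uses its own set.
#' @param thresholds A [classifier_thresholds()] object.
#' @return A data.frame with one row per classified (gene, tissue):
#'   `gene_id`, `tissue`, `category`, the six diffs, five ratios, relative
#'   cross positions, `signed_d14`, and `mode`.
#' @export
classify_table <- function(profiles, deg_set,
                           thresholds = classifier_thresholds()) {
  stopifnot(all(c("gene_id", "tissue", "m1", "m2", "m3", "m4") %in% names(profiles)))
  if (is.list(deg_set) && !is.data.frame(deg_set)) {
    keep <- mapply(function(g, t) g %in% (deg_set[[t]] %||% character(0)),
                   profiles$gene_id, profiles$tissue)
    wanted_ids <- unique(unlist(deg_set, use.names = FALSE))
  } else {
    keep <- profiles$gene_id %in% deg_set
    wanted_ids <- unique(deg_set)
  }
  missing <- setdiff(wanted_ids, profiles$gene_id)
  if (length(missing)) {
    stop("genes in deg_set absent from profiles: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10))
  }
  sub <- profiles[keep, , drop = FALSE]
  out <- cbind(
    sub[, c("gene_id", "tissue")],
    pairwise_diffs(as.matrix(sub[, c("m1", "m2", "m3", "m4")]),
                   min_d14 = thresholds$min_d14)
  )
  out$category <- vapply(seq_len(nrow(out)), function(i) {
    classify_gene(out[i, , drop = FALSE], thresholds = thresholds)
  }, character(1))
  out$mode <- rep(thresholds$mode, nrow(out))
  rownames(out) <- NULL
  out[order(out$tissue, out$gene_id),
      c("gene_id", "tissue", "category",
        "d12", "d13", "d14", "d23", "d24", "d34",
        "r12", "r13", "r23", "r24", "r34",
        "rel2", "rel3", "signed_d14", "mode")]
}

#' Tabulate inheritance calls by tissue and category
#'
#' @param calls Output of [classify_table()].
#' @return A list with `counts` (tissue x category table over the full
#'   category set) and `additive_fraction` (per-tissue fraction of
#'   classified, non-`UNCLASSIFIED` calls that are `ADDITIVE`).
#' @export
category_counts <- function(calls) {
  cats <- setdiff(inheritance_categories(), "NULL_GENE")
  tab <- table(factor(calls$tissue),
               factor(calls$category, levels = cats))
  classified <- calls[calls$category != "UNCLASSIFIED", , drop = FALSE]
  af <- tapply(classified$category == "ADDITIVE", classified$tissue, mean)
  list(counts = tab, additive_fraction = af)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
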