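#' Read a BED-like gene annotation
#'
#' Expects a TSV with columns `gene_id`, `chrom`, `start`, `end`,
#' `strand`, `biotype`. Coordinates are 1-based closed intervals by
#' default; set `zero_based = TRUE` to import BED-convention (0-based
#' half-open) starts.
#'
#' @param path File path.
#' @param zero_based Whether starts are 0-based half-open (BED).
#' @return A validated annotation data.frame (1-based closed).
#' @export
read_gene_annotation <- function(path, zero_based = FALSE) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene_id", "chrom", "start", "end", "strand", "biotype")
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop("annotation is missing columns: ", paste(missing, collapse = ", "))
  }
  if (zero_based) d$start <- d$start + 1L
  validate_annotation(d)
}

validate_annotation <- function(annotation) {
  if (anyDuplicated(annotation$gene_id)) stop("annotation has duplicated gene ids")
  if (any(annotation$start > annotation$end)) stop("annotation has start > end")
  if (any(annotation$start < 1)) stop("annotation coordinates must be positive (1-based)")
  if (!all(annotation$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  annotation
}

annotation_granges <- function(annotation) {
  GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start, end = annotation$end),
    strand = annotation$strand,
    gene_id = annotation$gene_id
  )
}

#' lncRNA / coding-gene neighbour pairs within a genomic window
#'
#' All same-chromosome (lncRNA, coding) pairs whose gap distance (bases
#' between closest ends; 0 if the genes overlap or are adjacent) is at
#' most `max_distance`, inclusive.
#'
#' @param annotation Annotation data.frame (1-based closed intervals; see
#'   [read_gene_annotation()]).
#' @param lnc_ids,coding_ids Gene ids of the lncRNAs and coding genes to
#'   pair. Every id must be annotated.
#' @param max_distance Maximum gap in bp (default 100000).
#' @return A data.frame with `lnc_id`, `coding_id`, `distance`.
#' @export
neighbor_pairs <- function(annotation, lnc_ids, coding_ids,
                           max_distance = 100000) {
  validate_annotation(annotation)
  unknown <- setdiff(c(lnc_ids, coding_ids), annotation$gene_id)
  if (length(unknown)) {
    stop("unannotated gene id(s): ", paste(unknown, collapse = ", "))
  }
  gr <- annotation_granges(annotation)
  names(gr) <- annotation$gene_id
  lnc <- gr[lnc_ids]
  cod <- gr[coding_ids]
  hits <- GenomicRanges::findOverlaps(lnc, cod, maxgap = max_distance,
                                      ignore.strand = TRUE)
  if (length(hits) == 0) {
    return(data.frame(lnc_id = character(0), coding_id = character(0),
                      distance = integer(0), stringsAsFactors = FALSE))
  }
  li <- S4Vectors::queryHits(hits)
  ci <- S4Vectors::subjectHits(hits)
  dist <- GenomicRanges::distance(lnc[li], cod[ci], ignore.strand = TRUE)
  keep <- !(lnc_ids[li] == coding_ids[ci])   # never pair a gene with itself
  out <- data.frame(lnc_id = lnc_ids[li], coding_id = coding_ids[ci],
                    distance = as.integer(dist),
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out <- unique(out)
  rownames(out) <- NULL
  out[order(out$lnc_id, out$coding_id), , drop = FALSE]
}

#' Direction concordance between paired DE genes
#'
#' For each neighbour pair with both members in the DE results and a
#' nonzero log2 fold change, records whether the fold changes have
#' opposite signs; zero-FC or absent pairs are excluded from the
#' denominator and counted separately. Reports both a per-pair fraction
#' and a per-lncRNA fraction (a lncRNA counts as opposite if the majority
#' of its usable pairs are opposite).
#'
#' @param pairs Output of [neighbor_pairs()].
#' @param de_results A [de_test()] table (or any data.frame with
#'   `gene_id` and `log2_fold_change`).
#' @return A list with `fraction_opposite_pairs`,
#'   `fraction_opposite_lncrnas`, `n_pairs_used`, `n_pairs_excluded`,
#'   and per-pair `detail`.
#' @export
direction_concordance <- function(pairs, de_results) {
  fc <- stats::setNames(de_results$log2_fold_change, de_results$gene_id)
  lfc <- fc[pairs$lnc_id]
  cfc <- fc[pairs$coding_id]
  usable <- !is.na(lfc) & !is.na(cfc) & lfc != 0 & cfc != 0
  detail <- data.frame(
    lnc_id = pairs$lnc_id, coding_id = pairs$coding_id,
    lnc_log2fc = as.numeric(lfc), coding_log2fc = as.numeric(cfc),
    usable = usable,
    opposite = ifelse(usable, sign(lfc) * sign(cfc) < 0, NA),
    stringsAsFactors = FALSE, row.names = NULL
  )
  used <- detail[detail$usable, , drop = FALSE]
  per_lnc <- if (nrow(used)) {
    tapply(used$opposite, used$lnc_id, function(z) mean(z) > 0.5)
  } else {
    logical(0)
  }
  list(
    fraction_opposite_pairs = if (nrow(used)) mean(used$opposite) else NA_real_,
    fraction_opposite_lncrnas = if (length(per_lnc)) mean(per_lnc) else NA_real_,
    n_pairs_used = nrow(used),
    n_pairs_excluded = sum(!usable),
    detail = detail
  )
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name  description  gene1  gene2 ...`.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3) stop("malformed GMT line: ", f[1])
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1)
  if (anyDuplicated(names(sets))) stop("duplicated gene-set names in GMT")
  sets
}

#' Fisher's exact gene-set over-representation
#'
#' One-sided (over-representation) Fisher's exact test of each gene set
#' against the query, within the stated gene universe, with
#' Benjamini-Hochberg adjustment across sets. Sets are intersected with
#' the universe before testing.
#'
#' @param query Character vector of genes of interest (must be a subset of
#'   `universe`, non-empty).
#' @param universe Character vector: all genes eligible for selection.
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @return A data.frame with one row per set: `set`, `set_size` (within
#'   universe), `overlap`, `expected`, `fold_enrichment`, `p_value`,
#'   `q_value`.
#' @export
fisher_enrichment <- function(query, universe, collection) {
  query <- unique(query)
  universe <- unique(universe)
  if (length(query) == 0) stop("empty query: over-representation is undefined")
  if (!all(query %in% universe)) {
    stop("query is not a subset of the universe: ",
         paste(utils::head(setdiff(query, universe), 5), collapse = ", "))
  }
  N <- length(universe)
  q <- length(query)
  rows <- lapply(names(collection), function(nm) {
    s <- intersect(collection[[nm]], universe)
    k <- length(intersect(s, query))
    # hypergeometric upper tail: P(overlap >= k)
    p <- stats::phyper(k - 1, length(s), N - length(s), q, lower.tail = FALSE)
    expected <- q * length(s) / N
    data.frame(set = nm, set_size = length(s), overlap = k,
               expected = expected,
               fold_enrichment = if (expected > 0) k / expected else NA_real_,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out[order(out$p_value, out$set), , drop = FALSE]
}
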