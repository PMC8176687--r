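#' Simulate study-shaped RNA-seq counts with planted inheritance modes
#'
#' Draws a negative-binomial count for every gene and sample. A gene's
#' expected log2 abundance in a sample is its planted group mean (see
#' [expected_group_means()]) plus per-gene tissue, sex and batch shifts;
#' the expected count is the sample's library size times the gene's share
#' of total abundance, so expected column sums equal the library sizes.
#' Reproducible: the same design, truth and config seed give identical
#' matrices.
#'
#' @param design Design table from [make_design()].
#' @param truth Truth table from [assign_gene_truth()].
#' @param config The [sim_config()] used (supplies library-size and
#'   effect-variance parameters and the seed).
#' @return A list with `counts` (integer matrix, genes x samples),
#'   `lib_sizes` (the drawn library sizes), `truth` and `design` as used,
#'   `expected_means` (noiseless group-mean profiles, genes x m1..m4) and
#'   `expected_counts` (the negative-binomial means, genes x samples).
#' @export
simulate_counts <- function(design, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(design) == 0 || nrow(truth) == 0) {
    stop("'design' and 'truth' must be non-empty")
  }
  n_genes <- nrow(truth)
  n_samples <- nrow(design)
  set.seed(config$seed + 1L)
  lib <- stats::rlnorm(n_samples, config$library_size_meanlog,
                       config$library_size_sdlog)

  gm <- t(vapply(seq_len(n_genes),
                 function(i) expected_group_means(truth[i, , drop = FALSE]),
                 numeric(4)))  # genes x 4 groups, log2 scale

  tissues <- unique(design$tissue)
  sexes <- unique(design$sex)
  batches <- unique(design$batch)
  t_eff <- matrix(stats::rnorm(n_genes * length(tissues), 0, config$tissue_effect_sd),
                  n_genes, dimnames = list(NULL, tissues))
  s_eff <- matrix(stats::rnorm(n_genes * length(sexes), 0, config$sex_effect_sd),
                  n_genes, dimnames = list(NULL, sexes))
  b_eff <- matrix(stats::rnorm(n_genes * length(batches), 0, config$batch_effect_sd),
                  n_genes, dimnames = list(NULL, batches))

  counts <- matrix(0L, n_genes, n_samples,
                   dimnames = list(truth$gene_id, design$sample_id))
  expected <- matrix(0, n_genes, n_samples,
                     dimnames = dimnames(counts))
  size <- 1 / truth$dispersion   # NB size parameter; dispersion -> 0 is Poisson
  for (j in seq_len(n_samples)) {
    x <- gm[, design$group[j]] +
      t_eff[, design$tissue[j]] + s_eff[, design$sex[j]] + b_eff[, design$batch[j]]
    abund <- 2^x
    mu <- lib[j] * abund / sum(abund)
    expected[, j] <- mu
    counts[, j] <- stats::rnbinom(n_genes, mu = mu, size = size)
  }
  storage.mode(counts) <- "integer"
  colnames(gm) <- paste0("m", 1:4)
  list(counts = counts, lib_sizes = stats::setNames(lib, design$sample_id),
       truth = truth, design = design, expected_means = gm,
       expected_counts = expected)
}

#' Write a simulation to disk
#'
#' Writes counts (TSV), design (CSV) and truth (TSV) with deterministic
#' column order, so reruns under the same seed are byte-identical.
#'
#' @param sim Output of [simulate_counts()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    design = file.path(dir, "design.csv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_counts(sim$counts, paths["counts"])
  write_design(sim$design, paths["design"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
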