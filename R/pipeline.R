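#' Default pipeline configuration
#'
#' All stage toggles and parameters of the end-to-end pipeline, with every
#' analysis threshold at its conventional default (CPM filter 0.5, FDR
#' 0.05, fold change 2 for tissue-specific sets, ratio thresholds 0.8 /
#' 0.2, 100 kb neighbour window). Amenable to (de)serialization as YAML.
#'
#' @param seed Top-level seed; per-stage seeds are derived from it.
#' @param out_dir Directory for pipeline artifacts.
#' @return A nested list (class `run_config`).
#' @export
default_run_config <- function(seed = 1L, out_dir = "crossmode_run") {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = list(simulate = TRUE, normalize = TRUE, de = TRUE,
                  classify = TRUE, context = FALSE),
    simulate = list(n_genes = 2000),
    input = list(counts = NULL, design = NULL, annotation = NULL,
                 gene_sets = NULL),
    normalize = list(cpm_threshold = 0.5, min_samples = 3, prior_count = 0.5,
                     m_trim = 0.30, a_trim = 0.05, batch_correct = TRUE),
    de = list(fdr = 0.05, min_abs_log2fc = 0, tissue_specific_fc = 1),
    classify = list(theta_high = 0.8, theta_low = 0.2, min_d14 = 0.5,
                    mode = "consistent"),
    context = list(max_distance = 100000)
  ), class = "run_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (nm in names(raw)) {
    if (is.list(cfg[[nm]]) && is.list(raw[[nm]])) {
      cfg[[nm]][names(raw[[nm]])] <- raw[[nm]]
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @param config A `run_config`.
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_run_config <- function(config) {
  st <- config$stages
  if (st$classify && !st$de) {
    stop("config error: classification requires the DE stage ",
         "(the classifier runs on purebred DEGs)")
  }
  if (st$de && !st$normalize) {
    stop("config error: DE requires the normalization stage")
  }
  if (!st$simulate && (is.null(config$input$counts) || is.null(config$input$design))) {
    stop("config error: with simulation disabled, input counts and design are required")
  }
  if (st$context && is.null(config$input$annotation)) {
    stop("config error: the context stage needs a gene annotation")
  }
  invisible(config)
}

stage_seeds <- function(seed, n = 5) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run the full reciprocal-cross expression pipeline
#'
#' Executes, in order: count simulation (or loading), CPM filtering + TMM
#' normalization + log-CPM + batch centering, purebred (1 vs 4) and
#' reciprocal-cross (2 vs 3) differential expression per tissue with a
#' cross-tissue DEG summary, inheritance classification of the purebred
#' DEGs, and (optionally) lncRNA-neighbour concordance and gene-set
#' enrichment. All artifacts are written under `config$out_dir` as
#' TSV/CSV/JSON with deterministic formatting, so a rerun with the same
#' config is byte-identical.
#'
#' @param config A `run_config` from [default_run_config()] or
#'   [read_run_config()].
#' @return The run report (also written as `report.json`): seed,
#'   parameters, per-stage row counts, category count table and artifact
#'   checksums.
#' @export
run_pipeline <- function(config = default_run_config()) {
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- stage_seeds(config$seed)
  report <- list(seed = config$seed, parameters = config[
    c("normalize", "de", "classify", "context")], counts = list())
  artifacts <- character(0)

  # --- stage 1: counts ------------------------------------------------
  if (config$stages$simulate) {
    sc <- sim_config(n_genes = config$simulate$n_genes, seed = seeds[1])
    design <- make_design()
    truth <- assign_gene_truth(sc)
    sim <- simulate_counts(design, truth, sc)
    counts <- sim$counts
    artifacts <- c(artifacts, write_simulation(sim, config$out_dir))
  } else {
    counts <- read_counts(config$input$counts)
    design <- read_design(config$input$design)
  }
  report$counts$samples <- ncol(counts)
  report$counts$genes_input <- nrow(counts)

  # --- stage 2: normalize ---------------------------------------------
  if (!config$stages$normalize) {
    return(finalize_report(report, artifacts, config))
  }
  nz <- config$normalize
  kept <- filter_low_expression(counts, nz$cpm_threshold, nz$min_samples)
  report$counts$genes_pass_filter <- nrow(kept)
  factors <- tmm_factors(kept, m_trim = nz$m_trim, a_trim = nz$a_trim)
  logmat <- log_cpm(kept, factors = factors, prior_count = nz$prior_count)
  if (nz$batch_correct && length(unique(design$batch)) > 1) {
    logmat <- batch_center(logmat, design)
  }
  fpath <- file.path(config$out_dir, "tmm_factors.tsv")
  utils::write.table(
    data.frame(sample_id = names(factors), factor = factors),
    fpath, sep = "\t", quote = FALSE, row.names = FALSE)
  lpath <- file.path(config$out_dir, "log_cpm.tsv")
  utils::write.table(
    data.frame(gene_id = rownames(logmat), logmat, check.names = FALSE),
    lpath, sep = "\t", quote = FALSE, row.names = FALSE)
  artifacts <- c(artifacts, fpath, lpath)

  # --- stage 3: differential expression -------------------------------
  if (!config$stages$de) {
    return(finalize_report(report, artifacts, config))
  }
  tissues <- unique(design$tissue)
  de_pure <- list(); de_cross <- list(); deg_sets <- list()
  for (t in tissues) {
    de_pure[[t]] <- de_test(logmat, design, t, 1, 4)
    de_cross[[t]] <- de_test(logmat, design, t, 3, 2)
    deg_sets[[t]] <- deg_select(de_pure[[t]], fdr = config$de$fdr,
                                min_abs_log2fc = config$de$min_abs_log2fc)
  }
  de_table <- do.call(rbind, c(de_pure, de_cross))
  rownames(de_table) <- NULL
  dpath <- file.path(config$out_dir, "de_results.tsv")
  utils::write.table(de_table, dpath, sep = "\t", quote = FALSE, row.names = FALSE)
  artifacts <- c(artifacts, dpath)
  venn <- degs_across_tissues(deg_sets)
  vpath <- file.path(config$out_dir, "deg_summary.json")
  jsonlite::write_json(
    list(region_sizes = as.list(venn$region_sizes),
         union_size = venn$union_size,
         shared_all = venn$shared_all,
         tissue_specific_sizes = lapply(venn$tissue_specific, length)),
    vpath, auto_unbox = TRUE, pretty = TRUE)
  artifacts <- c(artifacts, vpath)
  report$counts$purebred_degs_per_tissue <- lapply(deg_sets, length)
  report$counts$degs_shared_all_tissues <- length(venn$shared_all)

  # --- stage 4: inheritance classification ----------------------------
  if (config$stages$classify) {
    th <- classifier_thresholds(config$classify$theta_high,
                                config$classify$theta_low,
                                config$classify$min_d14,
                                config$classify$mode)
    profiles <- group_means(logmat, design)
    calls <- classify_table(profiles, deg_sets, thresholds = th)
    cpath <- file.path(config$out_dir, "inheritance_calls.tsv")
    utils::write.table(calls, cpath, sep = "\t", quote = FALSE, row.names = FALSE)
    tab <- category_counts(calls)
    tpath <- file.path(config$out_dir, "category_counts.tsv")
    utils::write.table(as.data.frame.matrix(tab$counts), tpath, sep = "\t",
                       quote = FALSE, col.names = NA)
    artifacts <- c(artifacts, cpath, tpath)
    report$counts$classified <- nrow(calls)
    report$category_counts <- lapply(
      as.list(as.data.frame.matrix(tab$counts)), stats::setNames,
      rownames(tab$counts))
    report$additive_fraction <- as.list(tab$additive_fraction)
  }

  # --- stage 5: genomic context ---------------------------------------
  if (config$stages$context) {
    ann <- read_gene_annotation(config$input$annotation)
    lnc <- ann$gene_id[ann$biotype == "lncRNA"]
    cod <- ann$gene_id[ann$biotype == "coding"]
    de1 <- do.call(rbind, de_pure)
    pairs <- neighbor_pairs(ann, intersect(lnc, de1$gene_id),
                            intersect(cod, de1$gene_id),
                            max_distance = config$context$max_distance)
    conc <- direction_concordance(pairs, de1)
    report$context <- conc[c("fraction_opposite_pairs",
                             "fraction_opposite_lncrnas",
                             "n_pairs_used", "n_pairs_excluded")]
    if (!is.null(config$input$gene_sets)) {
      sets <- read_gmt(config$input$gene_sets)
      enr <- fisher_enrichment(unique(unlist(deg_sets)), rownames(logmat), sets)
      epath <- file.path(config$out_dir, "enrichment.tsv")
      utils::write.table(enr, epath, sep = "\t", quote = FALSE, row.names = FALSE)
      artifacts <- c(artifacts, epath)
    }
  }

  finalize_report(report, artifacts, config)
}

finalize_report <- function(report, artifacts, config) {
  report$artifacts <- as.list(tools::md5sum(unname(artifacts)))
  rpath <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, rpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  report
}
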