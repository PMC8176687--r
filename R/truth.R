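#' Inheritance categories
#'
#' The closed set of per-gene expression-inheritance categories used
#' throughout the package. `NULL_GENE` marks non-differentially-expressed
#' filler genes in simulations; `UNCLASSIFIED` is reserved for classifier
#' guard failures (purebred separation below the minimum) and is not a
#' biological class.
#'
#' @return Character vector of category names.
#' @export
inheritance_categories <- function() {
  c("NULL_GENE", "ADDITIVE",
    "MATERNAL_TAURINE", "MATERNAL_INDICINE",
    "PATERNAL_TAURINE", "PATERNAL_INDICINE",
    "TAURINE_DOMINANT_ACTIVATION", "TAURINE_DOMINANT_INHIBITION",
    "INDICINE_DOMINANT_ACTIVATION", "INDICINE_DOMINANT_INHIBITION",
    "COMPLEX", "UNCLASSIFIED")
}

poe_categories <- function() {
  c("MATERNAL_TAURINE", "MATERNAL_INDICINE",
    "PATERNAL_TAURINE", "PATERNAL_INDICINE",
    "TAURINE_DOMINANT_ACTIVATION", "TAURINE_DOMINANT_INHIBITION",
    "INDICINE_DOMINANT_ACTIVATION", "INDICINE_DOMINANT_INHIBITION")
}

#' Simulation configuration
#'
#' Bundles and validates all knobs of the synthetic count generator. The
#' defaults emulate a mid-gestation reciprocal-cross fetal study at desk
#' scale: most genes not differentially expressed between the purebreds,
#' the differentially expressed majority additive, and a small minority in
#' each parent-of-origin / dominance class so that every class is
#' exercised.
#'
#' @param n_genes Number of genes to simulate.
#' @param category_proportions Named numeric vector of category
#'   probabilities over [inheritance_categories()] (excluding
#'   `UNCLASSIFIED`); must sum to 1.
#' @param effect_size_range Range of |breed effect| (purebred log2
#'   separation, Bt minus Bi) for non-null genes, drawn uniformly.
#' @param baseline_mean,baseline_sd Normal parameters of per-gene baseline
#'   log2 relative abundance (roughly log2 CPM scale).
#' @param library_size_meanlog,library_size_sdlog Log-normal parameters of
#'   per-sample library size; defaults give desk-scale libraries of about
#'   1-3 million reads.
#' @param dispersion_meanlog,dispersion_sdlog Log-normal parameters of the
#'   per-gene negative-binomial dispersion.
#' @param tissue_effect_sd,sex_effect_sd,batch_effect_sd Standard
#'   deviations (log2 scale) of per-gene tissue, sex and batch shifts.
#' @param seed Integer seed controlling all randomness downstream.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       category_proportions = c(
                         NULL_GENE = 0.60, ADDITIVE = 0.30,
                         MATERNAL_TAURINE = 0.01, MATERNAL_INDICINE = 0.01,
                         PATERNAL_TAURINE = 0.01, PATERNAL_INDICINE = 0.01,
                         TAURINE_DOMINANT_ACTIVATION = 0.01,
                         TAURINE_DOMINANT_INHIBITION = 0.01,
                         INDICINE_DOMINANT_ACTIVATION = 0.01,
                         INDICINE_DOMINANT_INHIBITION = 0.01,
                         COMPLEX = 0.02),
                       effect_size_range = c(1, 4),
                       baseline_mean = 5, baseline_sd = 2,
                       library_size_meanlog = log(1.7e6),
                       library_size_sdlog = 0.18,
                       dispersion_meanlog = log(0.05),
                       dispersion_sdlog = 0.5,
                       tissue_effect_sd = 2,
                       sex_effect_sd = 0.2,
                       batch_effect_sd = 0.5,
                       seed = 1L) {
  if (length(n_genes) != 1 || n_genes < 0 || n_genes != round(n_genes)) {
    stop("config error: 'n_genes' must be a non-negative integer")
  }
  allowed <- setdiff(inheritance_categories(), "UNCLASSIFIED")
  if (is.null(names(category_proportions)) ||
      !all(names(category_proportions) %in% allowed)) {
    stop("config error: 'category_proportions' must be named with categories from inheritance_categories()")
  }
  if (any(category_proportions < 0)) {
    stop("config error: category proportions must be non-negative")
  }
  if (abs(sum(category_proportions) - 1) > 1e-9) {
    stop("config error: category proportions must sum to 1 (got ",
         format(sum(category_proportions)), ")")
  }
  if (length(effect_size_range) != 2 || any(effect_size_range <= 0) ||
      effect_size_range[1] > effect_size_range[2]) {
    stop("config error: 'effect_size_range' must be positive and increasing")
  }
  for (nm in c("baseline_sd", "library_size_sdlog", "dispersion_sdlog",
               "tissue_effect_sd", "sex_effect_sd", "batch_effect_sd")) {
    if (get(nm) < 0) stop("config error: '", nm, "' must be >= 0")
  }
  structure(list(
    n_genes = as.integer(n_genes),
    category_proportions = category_proportions,
    effect_size_range = effect_size_range,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    library_size_meanlog = library_size_meanlog,
    library_size_sdlog = library_size_sdlog,
    dispersion_meanlog = dispersion_meanlog,
    dispersion_sdlog = dispersion_sdlog,
    tissue_effect_sd = tissue_effect_sd,
    sex_effect_sd = sex_effect_sd,
    batch_effect_sd = batch_effect_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Assign planted inheritance truth to simulated genes
#'
#' Draws each gene's inheritance category, signed breed effect (Bt minus
#' Bi, log2 units), baseline abundance and negative-binomial dispersion.
#' The breed effect is exactly 0 for `NULL_GENE` rows and its sign is
#' constrained by the category where the category fixes which purebred is
#' the high expresser (e.g. `MATERNAL_TAURINE` genes are high in Bt).
#' `COMPLEX` genes additionally carry relative cross positions
#' (`cross2_rel`, `cross3_rel`), rejection-sampled to fall outside every
#' consistent-mode rule region.
#'
#' @param config A [sim_config()].
#' @return A data.frame (truth table) with columns `gene_id`, `category`,
#'   `breed_effect`, `baseline`, `dispersion`, `cross2_rel`, `cross3_rel`.
#' @export
assign_gene_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  empty <- data.frame(
    gene_id = character(0), category = character(0),
    breed_effect = numeric(0), baseline = numeric(0),
    dispersion = numeric(0), cross2_rel = numeric(0), cross3_rel = numeric(0),
    stringsAsFactors = FALSE
  )
  if (n == 0) return(empty)
  set.seed(config$seed)
  p <- config$category_proportions
  category <- sample(names(p), n, replace = TRUE, prob = p)
  effect <- stats::runif(n, config$effect_size_range[1], config$effect_size_range[2])
  # categories tied to the taurine purebred being the high expresser need
  # breed_effect > 0; those tied to indicine need < 0; the rest flip a coin
  sign_pos <- c("MATERNAL_TAURINE", "PATERNAL_TAURINE",
                "TAURINE_DOMINANT_ACTIVATION", "INDICINE_DOMINANT_INHIBITION")
  sign_neg <- c("MATERNAL_INDICINE", "PATERNAL_INDICINE",
                "TAURINE_DOMINANT_INHIBITION", "INDICINE_DOMINANT_ACTIVATION")
  sgn <- ifelse(category %in% sign_pos, 1,
         ifelse(category %in% sign_neg, -1,
                sample(c(-1, 1), n, replace = TRUE)))
  effect <- effect * sgn
  effect[category == "NULL_GENE"] <- 0
  baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
  dispersion <- stats::rlnorm(n, config$dispersion_meanlog, config$dispersion_sdlog)
  cross2 <- rep(NA_real_, n)
  cross3 <- rep(NA_real_, n)
  idx <- which(category == "COMPLEX")
  if (length(idx)) {
    th <- classifier_thresholds()
    for (i in idx) {
      repeat {
        r2 <- stats::runif(1, -0.25, 1.25)
        r3 <- stats::runif(1, -0.25, 1.25)
        if (classify_relpos(r2, r3, sign(effect[i]), th) == "COMPLEX") break
      }
      cross2[i] <- r2
      cross3[i] <- r3
    }
  }
  data.frame(
    gene_id = sprintf("gene%05d", seq_len(n)),
    category = category,
    breed_effect = effect,
    baseline = baseline,
    dispersion = dispersion,
    cross2_rel = cross2,
    cross3_rel = cross3,
    stringsAsFactors = FALSE
  )
}

#' Noiseless group means implied by a planted category
#'
#' Returns the expected log2 abundance of genetic groups 1-4 for one truth
#' row: the geometry of each inheritance pattern around the gene's
#' baseline. Purebreds sit at baseline +/- effect/2; additive crosses sit
#' at the midpoint; maternally driven crosses match their dam's purebred;
#' paternally driven crosses match their sire's; dominant categories place
#' both crosses at the dominant breed's purebred level. `COMPLEX` rows use
#' their stored relative cross positions and error if these are absent.
#'
#' @param truth_row One row of the truth table from [assign_gene_truth()].
#' @return Named numeric vector `m1`..`m4` (log2 scale).
#' @examples
#' tr <- data.frame(category = "ADDITIVE", breed_effect = 3, baseline = 8)
#' expected_group_means(tr)   # 9.5 8.0 8.0 6.5
#' @export
expected_group_means <- function(truth_row) {
  cat <- as.character(truth_row$category)
  b <- truth_row$baseline
  e <- truth_row$breed_effect
  m1 <- b + e / 2
  m4 <- b - e / 2
  cross <- switch(cat,
    NULL_GENE = c(b, b),
    ADDITIVE = c(b, b),
    # group 2's dam is Bt (purebred 1); group 3's dam is Bi (purebred 4)
    MATERNAL_TAURINE = ,
    MATERNAL_INDICINE = c(m1, m4),
    # group 2's sire is Bi (purebred 4); group 3's sire is Bt (purebred 1)
    PATERNAL_TAURINE = ,
    PATERNAL_INDICINE = c(m4, m1),
    TAURINE_DOMINANT_ACTIVATION = ,
    TAURINE_DOMINANT_INHIBITION = c(m1, m1),
    INDICINE_DOMINANT_ACTIVATION = ,
    INDICINE_DOMINANT_INHIBITION = c(m4, m4),
    COMPLEX = {
      if (is.null(truth_row$cross2_rel) || is.na(truth_row$cross2_rel)) {
        stop("COMPLEX truth rows need 'cross2_rel'/'cross3_rel' positions")
      }
      c(m4 + truth_row$cross2_rel * (m1 - m4),
        m4 + truth_row$cross3_rel * (m1 - m4))
    },
    stop("unknown inheritance category: ", cat)
  )
  c(m1 = m1, m2 = cross[1], m3 = cross[2], m4 = m4)
}
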