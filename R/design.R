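#' Genetic group codebook for a reciprocal-cross design
#'
#' The four genetic groups of a purebred-plus-reciprocal-cross design are
#' conventionally labelled by digits, sire breed listed first:
#' 1 = Bt x Bt, 2 = Bi x Bt, 3 = Bt x Bi, 4 = Bi x Bi, where Bt is the
#' taurine and Bi the indicine breed. Group 1 and 4 are the purebreds;
#' groups 2 and 3 are the reciprocal crosses, differing only in which breed
#' was the sire.
#'
#' @return A data.frame with columns `group` (integer code 1-4), `sire`
#'   and `dam` (breed of each parent, `"Bt"` or `"Bi"`), and `label`
#'   (e.g. `"BixBt"`, sire first).
#' @examples
#' genetic_groups()
#' @export
genetic_groups <- function() {
  data.frame(
    group = 1:4,
    sire = c("Bt", "Bi", "Bt", "Bi"),
    dam = c("Bt", "Bt", "Bi", "Bi"),
    label = c("BtxBt", "BixBt", "BtxBi", "BixBi"),
    stringsAsFactors = FALSE
  )
}

#' Build a full-factorial sample design table
#'
#' Crosses tissues, genetic groups, sexes and replicates into a sample
#' sheet with one row per sample. The default arguments emulate a
#' five-tissue, four-group, two-sex, three-replicate fetal study: 120
#' samples in total, 24 per tissue.
#'
#' @param tissues Character vector of tissue names.
#' @param groups Integer vector of genetic group codes (subset of 1:4, see
#'   [genetic_groups()]).
#' @param sexes Character vector of sex labels.
#' @param replicates Number of replicates per (tissue, group, sex) cell.
#' @param batch_rule How batches are assigned: `"by_replicate"` (batch =
#'   replicate index, emulating samples split across sequencing runs) or
#'   `"single"` (one batch).
#' @return A data.frame with columns `sample_id`, `tissue`, `group`,
#'   `sire`, `dam`, `sex`, `replicate`, `batch`. Rows are ordered by
#'   tissue, then group, sex, replicate; `sample_id` is unique.
#' @examples
#' d <- make_design()
#' nrow(d)                      # 120
#' table(d$tissue)              # 24 per tissue
#' @export
make_design <- function(tissues = c("brain", "liver", "lung", "muscle", "placenta"),
                        groups = 1:4,
                        sexes = c("M", "F"),
                        replicates = 3,
                        batch_rule = c("by_replicate", "single")) {
  batch_rule <- match.arg(batch_rule)
  if (length(tissues) == 0 || length(groups) == 0 || length(sexes) == 0) {
    stop("invalid design: 'tissues', 'groups' and 'sexes' must all be non-empty")
  }
  if (anyDuplicated(tissues) || anyDuplicated(groups) || anyDuplicated(sexes)) {
    stop("invalid design: factor levels must be unique")
  }
  if (length(replicates) != 1 || replicates < 1 || replicates != round(replicates)) {
    stop("invalid design: 'replicates' must be a positive integer")
  }
  gg <- genetic_groups()
  if (!all(groups %in% gg$group)) {
    stop("invalid design: 'groups' must be a subset of 1:4")
  }
  d <- expand.grid(
    replicate = seq_len(replicates),
    sex = sexes,
    group = groups,
    tissue = tissues,
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
  d <- d[, c("tissue", "group", "sex", "replicate")]
  d <- d[order(match(d$tissue, tissues), match(d$group, groups),
               match(d$sex, sexes), d$replicate), , drop = FALSE]
  d$sire <- gg$sire[match(d$group, gg$group)]
  d$dam <- gg$dam[match(d$group, gg$group)]
  d$batch <- if (batch_rule == "single") "b1" else paste0("b", d$replicate)
  d$sample_id <- sprintf("%s_g%d_%s_r%d", d$tissue, d$group, d$sex, d$replicate)
  rownames(d) <- NULL
  d[, c("sample_id", "tissue", "group", "sire", "dam", "sex", "replicate", "batch")]
}

#' Write / read a design table as CSV
#'
#' @param design A design data.frame from [make_design()].
#' @param path File path.
#' @return `write_design` returns `path` invisibly; `read_design` returns
#'   the design data.frame.
#' @export
write_design <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "tissue", "group", "sex", "replicate", "batch")
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop("design file is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(d$sample_id)) stop("design file has duplicated sample_id values")
  d
}
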