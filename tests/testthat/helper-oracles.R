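# Independent oracles used across test files. Each is written directly
# from first principles / the published rule text, deliberately not
# sharing code paths with the package implementation.

# Rule-table oracle for the inheritance classifier, working on the raw
# group means m1..m4 and plain absolute differences.
oracle_classify <- function(m1, m2, m3, m4, mode = "consistent",
                            hi = 0.8, lo = 0.2, min_sep = 0.5) {
  d14 <- abs(m1 - m4)
  if (d14 < min_sep || d14 == 0) return("UNCLASSIFIED")
  q23 <- abs(m2 - m3) / d14
  q12 <- abs(m1 - m2) / d14
  q13 <- abs(m1 - m3) / d14
  q24 <- abs(m2 - m4) / d14
  q34 <- abs(m3 - m4) / d14
  bt_high <- m1 > m4
  if (mode == "as_printed") {
    # published inequality sets, printed order, first match wins; the
    # duplicated eighth label corrected to indicine dominant activation
    if (q23 > hi && q12 < lo && q34 < lo && bt_high) return("MATERNAL_TAURINE")
    if (q23 > hi && q12 < lo && q34 < lo && !bt_high) return("MATERNAL_INDICINE")
    if (q23 > hi && q13 < lo && q24 < lo && bt_high) return("PATERNAL_TAURINE")
    if (q23 > hi && q13 < lo && q24 < lo && !bt_high) return("PATERNAL_INDICINE")
    if (q23 < lo && q24 < hi && q34 < hi && !bt_high) return("TAURINE_DOMINANT_INHIBITION")
    if (q23 < lo && q24 < hi && q34 < hi && bt_high) return("TAURINE_DOMINANT_ACTIVATION")
    if (q23 < lo && q12 < hi && q13 < hi && bt_high) return("INDICINE_DOMINANT_INHIBITION")
    if (q23 < lo && q12 < hi && q13 < hi && !bt_high) return("INDICINE_DOMINANT_ACTIVATION")
    return("COMPLEX")
  }
  # consistent mode: positions of the crosses on the purebred axis
  # (0 = the Bi purebred, 1 = the Bt purebred)
  p2 <- (m2 - m4) / (m1 - m4)
  p3 <- (m3 - m4) / (m1 - m4)
  if (q23 > hi && p2 > 1 - lo && p3 < lo) {
    return(if (bt_high) "MATERNAL_TAURINE" else "MATERNAL_INDICINE")
  }
  if (q23 > hi && p3 > 1 - lo && p2 < lo) {
    return(if (bt_high) "PATERNAL_TAURINE" else "PATERNAL_INDICINE")
  }
  if (q23 < lo && p2 > 1 - lo && p3 > 1 - lo) {
    return(if (bt_high) "TAURINE_DOMINANT_ACTIVATION" else "TAURINE_DOMINANT_INHIBITION")
  }
  if (q23 < lo && p2 < lo && p3 < lo) {
    return(if (!bt_high) "INDICINE_DOMINANT_ACTIVATION" else "INDICINE_DOMINANT_INHIBITION")
  }
  if (q23 < lo && p2 >= lo && p2 <= 1 - lo && p3 >= lo && p3 <= 1 - lo) {
    return("ADDITIVE")
  }
  "COMPLEX"
}

# Step-by-step TMM oracle, following the published method definition:
# double-trimmed, inverse-variance-weighted mean of M-values against the
# sample whose scaled upper quartile is closest to the mean upper
# quartile; factors rescaled to geometric mean 1.
oracle_tmm <- function(counts, lib = colSums(counts),
                       m_trim = 0.30, a_trim = 0.05) {
  uq <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(uq - mean(uq)))
  xr <- counts[, ref] / lib[ref]
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    xj <- counts[, j] / lib[j]
    keep0 <- counts[, j] > 0 & counts[, ref] > 0
    M <- log2(xj[keep0] / xr[keep0])
    A <- 0.5 * log2(xj[keep0] * xr[keep0])
    # delta-method binomial variance of M; weights are its inverse
    v <- (lib[j] - counts[keep0, j]) / (lib[j] * counts[keep0, j]) +
      (lib[ref] - counts[keep0, ref]) / (lib[ref] * counts[keep0, ref])
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; v <- v[fin]
    if (max(abs(M)) < 1e-6) { f[j] <- 1; next }
    n <- length(M)
    loM <- floor(n * m_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * a_trim) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    fj <- sum(M[keep] / v[keep]) / sum(1 / v[keep])
    if (!is.finite(fj)) fj <- 0
    f[j] <- 2^fj
  }
  f / exp(mean(log(f)))
}

# Brute-force Benjamini-Hochberg step-up from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(o == i)
    q[i] <- min(1, min(p[o][seq(rank_i, m)] * m / seq(rank_i, m)))
  }
  q
}

# Hypergeometric upper-tail by direct summation of choose() terms:
# P(overlap >= k) drawing q from a universe of N with K marked.
oracle_hyper_tail <- function(k, K, N, q) {
  kk <- k:min(K, q)
  sum(choose(K, kk) * choose(N - K, q - kk)) / choose(N, q)
}

# All-pairs brute-force neighbour search on 1-based closed intervals.
oracle_neighbors <- function(annotation, lnc_ids, coding_ids, max_distance) {
  rows <- list()
  for (l in lnc_ids) {
    for (c in coding_ids) {
      if (l == c) next
      a <- annotation[annotation$gene_id == l, ]
      b <- annotation[annotation$gene_id == c, ]
      if (a$chrom != b$chrom) next
      gap <- max(0, max(a$start, b$start) - min(a$end, b$end) - 1)
      if (gap <= max_distance) {
        rows[[length(rows) + 1]] <- data.frame(
          lnc_id = l, coding_id = c, distance = as.integer(gap),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lnc_id = character(0), coding_id = character(0),
               distance = integer(0), stringsAsFactors = FALSE)
  out <- out[order(out$lnc_id, out$coding_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
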