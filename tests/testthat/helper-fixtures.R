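# Small configurations and independent oracles used across the suite.

# Compact synthetic profile: same structure as the default, fewer genes/cells.
small_sc_config <- function(seed = 1L, n_cells = 60L, ...) {
  synthetic_sc_config(
    n_genes = 60L,
    n_cells_per_type = n_cells,
    planted_markers = list(
      Mac_SPP1 = data.frame(gene = 1:3, fc = 16),
      Mac_C1QC = data.frame(gene = 4:7, fc = 16),
      Tcell    = data.frame(gene = 8:9, fc = 16)),
    macrophage_shared_markers = data.frame(gene = 11:12, fc = 6),
    broad_markers = data.frame(gene = 14:16, fc = 6),
    seed = seed, ...)
}

# All fold changes at 1: every cell type shares one expression distribution.
null_sc_config <- function(seed = 1L, n_genes = 100L, n_cells = 100L) {
  synthetic_sc_config(
    n_genes = n_genes, n_cells_per_type = n_cells,
    planted_markers = list(
      Mac_SPP1 = data.frame(gene = 1:5, fc = 1),
      Mac_C1QC = data.frame(gene = 6:13, fc = 1)),
    macrophage_shared_markers = data.frame(gene = 21:25, fc = 1),
    broad_markers = data.frame(gene = 31:38, fc = 1),
    other_mac_fc = 1, seed = seed)
}

# Literal per-gene z-score loop: the independent scoring oracle.
oracle_signature_score <- function(mat, genes, log_transform = TRUE) {
  m <- if (log_transform) log2(mat + 1) else mat
  hits <- rownames(m)[toupper(rownames(m)) %in% toupper(genes)]
  z <- matrix(NA_real_, nrow = length(hits), ncol = ncol(m))
  kept <- logical(length(hits))
  for (i in seq_along(hits)) {
    v <- m[hits[i], ]
    if (sd(v) == 0) next
    kept[i] <- TRUE
    z[i, ] <- (v - mean(v)) / sd(v)
  }
  colMeans(z[kept, , drop = FALSE])
}

# Direct Benjamini-Hochberg step-up procedure.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Pair-counting AUROC (ties count half).
oracle_auroc <- function(score, positive) {
  pos <- score[positive]
  neg <- score[!positive]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Rank-sum statistic by direct enumeration: W = (number of (target, rest)
# pairs won) counting ties half, i.e. the Mann-Whitney U for target vs rest.
oracle_rank_sum_u <- function(x, y) {
  tot <- 0
  for (xi in x) tot <- tot + sum(xi > y) + 0.5 * sum(xi == y)
  tot
}
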