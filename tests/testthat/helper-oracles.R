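# Independent reference implementations used as test oracles. These are
# deliberately written as plain, slow, loop-based code, separate from the
# package's vectorized paths.

# Spearman via explicit rank-then-Pearson, p from the Pearson t-test on the
# ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  r <- cor(rx, ry)
  ct <- cor.test(rx, ry, method = "pearson")
  list(r = r, p = ct$p.value)
}

# Exhaustive permutation p-value for the two-sided Wilcoxon rank-sum test:
# all assignments of group-1 labels, tail probability of |W - E[W]|.
oracle_wilcox_perm <- function(x, g1) {
  r <- rank(x, ties.method = "average")
  n1 <- sum(g1)
  w_obs <- sum(r[g1])
  mu <- n1 * (length(x) + 1) / 2
  combos <- utils::combn(seq_along(x), n1)
  w_all <- colSums(matrix(r[combos], nrow = n1))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Geometric mean in log space.
oracle_geomean <- function(v) exp(mean(log(v)))

# Brute-force single-sample KS walk for the GSVA-style score: every step is
# spelled out for one sample and one set.
oracle_gsva_sample <- function(x, members, sample_j, tau = 1,
                               mode = "max_dev") {
  p <- nrow(x)
  n <- ncol(x)
  z <- numeric(p)
  for (i in seq_len(p)) {
    h <- sd(x[i, ]) / 4
    if (!is.finite(h) || h <= 0) h <- 1e-8
    acc <- 0
    for (k in seq_len(n)) acc <- acc + pnorm((x[i, sample_j] - x[i, k]) / h)
    z[i] <- acc / n
  }
  ord <- order(z, decreasing = TRUE)
  pos <- match(seq_len(p), ord)
  stat <- abs(p / 2 - pos)
  memb <- rownames(x) %in% members
  m <- sum(memb)
  walk <- numeric(p)
  run <- 0
  wsum <- sum(stat[memb]^tau)
  for (step in seq_len(p)) {
    g <- ord[step]
    if (memb[g]) {
      run <- run + stat[g]^tau / wsum
    } else {
      run <- run - 1 / (p - m)
    }
    walk[step] <- run
  }
  vmax <- max(c(0, walk))
  vmin <- min(c(0, walk))
  if (mode == "max_dev") {
    if (vmax >= -vmin) vmax else vmin
  } else {
    vmax + vmin
  }
}

# AUC by explicit comparison of every positive/negative pair, ties half.
oracle_auc_pairs <- function(scores, pos) {
  sp <- scores[pos]
  sn <- scores[!pos]
  total <- 0
  for (a in sp) {
    for (b in sn) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
  }
  total / (length(sp) * length(sn))
}

# One-sided over-representation p by direct hypergeometric tail summation:
# P(X >= a) with K signature genes, k top genes, N universe genes.
oracle_hyper_tail <- function(a, K, k, N) {
  i <- a:min(K, k)
  sum(exp(lchoose(K, i) + lchoose(N - K, k - i) - lchoose(N, k)))
}

# small dense cell-by-gene expr_mat with default ids
toy_cells <- function(m, layer = "raw_counts") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("c%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("g%03d", seq_len(ncol(m)))
  expr_mat(m, layer_tag = layer, orientation = "cell_by_gene")
}

# a stemness_result wrapper around an arbitrary score vector, for feeding
# compute_gx directly
as_stemness <- function(cell_ids, score) {
  structure(
    tibble::tibble(cell_id = cell_ids,
                   gene_counts = NA_integer_,
                   gcs = score, score = score),
    class = c("stemness_result", "tbl_df", "tbl", "data.frame")
  )
}
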