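# CRISPR immune-screen aggregation: per-dataset log-fold changes and
# z-normalization, cross-dataset mean-z ranking with a missing-data mask,
# top-k% immune-resistance sets, and over-representation testing of a
# signature against them.

#' CRISPR screen panel container
#'
#' A gene x dataset matrix of normalized z-scores with `NA` marking entries
#' a screen did not cover. Lower z = knocking the gene out improves the
#' immune response (immune-resistance gene).
#'
#' @param z Numeric matrix, genes x datasets, with row and column names;
#'   `NA` = missing.
#' @return A `crispr_panel` with elements `z` and `mask` (TRUE = observed).
#' @export
crispr_panel <- function(z) {
  z <- as.matrix(z)
  if (is.null(rownames(z)) || is.null(colnames(z))) {
    stop("crispr_panel needs gene and dataset identifiers", call. = FALSE)
  }
  if (anyDuplicated(rownames(z))) {
    stop("duplicate gene ids in crispr panel", call. = FALSE)
  }
  structure(list(z = z, mask = !is.na(z)), class = "crispr_panel")
}

#' @export
print.crispr_panel <- function(x, ...) {
  cat(sprintf("<crispr_panel> %d genes x %d datasets (%.1f%% observed)\n",
              nrow(x$z), ncol(x$z), 100 * mean(x$mask)))
  invisible(x)
}

#' Gene-level log2 fold changes from paired sgRNA counts
#'
#' `log2((treat/treat_total + pc/treat_total) / (ctrl/ctrl_total +
#' pc/ctrl_total))` per sgRNA — i.e. pseudocounted library-size-normalized
#' abundances — collapsed to gene level by the mean over each gene's
#' guides.
#'
#' @param treat_counts,ctrl_counts Non-negative sgRNA read counts over a
#'   matched guide universe (treatment = under immune pressure).
#' @param genes Gene assignment per sgRNA (one gene per guide; a single
#'   guide per gene is fine).
#' @param pseudocount Pseudocount added to each raw count (default 1).
#' @return A tibble: `gene`, `lfc`, `n_guides`.
#' @export
lfc_from_counts <- function(treat_counts, ctrl_counts, genes,
                            pseudocount = 1) {
  stopifnot(length(treat_counts) == length(ctrl_counts),
            length(genes) == length(treat_counts),
            all(treat_counts >= 0), all(ctrl_counts >= 0))
  tt <- sum(treat_counts)
  tc <- sum(ctrl_counts)
  if (tt == 0 || tc == 0) {
    stop("zero total reads in a library", call. = FALSE)
  }
  lfc <- log2(((treat_counts + pseudocount) / tt) /
                ((ctrl_counts + pseudocount) / tc))
  tibble::tibble(gene = as.character(genes), lfc = lfc) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(lfc = mean(.data$lfc), n_guides = dplyr::n(),
                     .groups = "drop")
}

#' Z-normalize per-dataset log-fold changes
#'
#' Standardizes a dataset's LFC column over its observed genes —
#' `(x - mean) / sd`, or `(x - median) / mad` with `robust = TRUE` — so
#' datasets from different studies are comparable; invariant to per-dataset
#' affine transforms of the input. The sign convention is inherited from
#' the input (negative = knockout sensitizes the tumor to immune killing).
#'
#' @param lfc Numeric vector with `NA` for missing genes.
#' @param robust Use median/MAD instead of mean/SD.
#' @return Numeric vector of z-scores (NA preserved).
#' @export
zscore_normalize <- function(lfc, robust = FALSE) {
  obs <- !is.na(lfc)
  if (sum(obs) < 2) stop("need at least 2 observed values", call. = FALSE)
  if (robust) {
    ctr <- median(lfc[obs])
    scl <- stats::mad(lfc[obs])
  } else {
    ctr <- mean(lfc[obs])
    scl <- sd(lfc[obs])
  }
  if (scl == 0) stop("constant column: zero scale", call. = FALSE)
  (lfc - ctr) / scl
}

#' Rank genes by mean z across datasets
#'
#' Per gene, the mean z over observed datasets only (screens do not share a
#' gene universe; a gene is ranked on whatever evidence exists, subject to
#' `min_observed`). Rank 1 = lowest mean z = most immune-resistant. Ties
#' break lexicographically by gene id for reproducibility.
#'
#' @param panel A [crispr_panel()].
#' @param min_observed Minimum observed datasets for a gene to be ranked
#'   (default 1).
#' @return A tibble sorted by rank: `gene`, `mean_z`, `n_observed`,
#'   `rank`.
#' @export
rank_genes <- function(panel, min_observed = 1) {
  stopifnot(inherits(panel, "crispr_panel"))
  n_obs <- rowSums(panel$mask)
  mean_z <- rowSums(panel$z, na.rm = TRUE) / pmax(n_obs, 1)
  keep <- n_obs >= min_observed
  if (any(!keep)) {
    ss_log("rank_genes: %d genes below min_observed dropped", sum(!keep))
  }
  tb <- tibble::tibble(
    gene = rownames(panel$z)[keep],
    mean_z = unname(mean_z[keep]),
    n_observed = unname(as.integer(n_obs[keep]))
  )
  tb <- dplyr::arrange(tb, .data$mean_z, .data$gene)
  tb$rank <- seq_len(nrow(tb))
  tb
}

#' Top-k% immune-resistance gene set
#'
#' The first `floor(n_ranked * pct / 100)` genes of a ranking — the floor
#' convention, so a 22,505-gene universe yields sets of 225, 450 and 675
#' genes at 1, 2 and 3 percent.
#'
#' @param ranked A ranked tibble from [rank_genes()].
#' @param pct Percentage of the ranked universe (0 < pct <= 100).
#' @return Character vector of gene ids in rank order.
#' @export
topk_set <- function(ranked, pct) {
  stopifnot(pct > 0, pct <= 100, "rank" %in% names(ranked))
  k <- floor(nrow(ranked) * pct / 100)
  ranked$gene[seq_len(k)]
}

#' Over-representation of a signature among top-ranked genes
#'
#' One-sided Fisher's exact test on the 2x2 table of signature membership
#' versus top-set membership over the screen's gene universe. Signature
#' genes absent from the universe are dropped first (count logged). The
#' overlap is returned in top-set (rank) order.
#'
#' @param signature Character vector of signature genes.
#' @param topk Character vector from [topk_set()] (rank-ordered).
#' @param universe Character vector: all ranked genes.
#' @return A list: `overlap`, `odds_ratio`, `p_value`, `contingency`.
#' @export
enrichment_test <- function(signature, topk, universe) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  stopifnot(all(topk %in% universe))
  dropped <- sum(!signature %in% universe)
  if (dropped > 0) {
    ss_log("enrichment_test: %d signature genes absent from the universe dropped",
           dropped)
  }
  sig <- intersect(signature, universe)
  overlap <- topk[topk %in% sig]
  a <- length(overlap)
  b <- length(sig) - a
  cc <- length(topk) - a
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, b, cc, d), nrow = 2,
                dimnames = list(signature = c("in", "out"),
                                topk = c("in", "out")))
  ft <- fisher.test(tab, alternative = "greater")
  list(
    overlap = overlap,
    odds_ratio = unname(ft$estimate),
    p_value = ft$p.value,
    contingency = tab
  )
}

#' Plot a CRISPR mean-z ranking
#'
#' Mean z by rank, with an optional gene set highlighted.
#'
#' @param ranked A tibble from [rank_genes()].
#' @param highlight Optional character vector of genes to mark.
#' @return A ggplot.
#' @export
plot_crispr_ranking <- function(ranked, highlight = NULL) {
  ranked <- dplyr::mutate(ranked,
                          highlighted = .data$gene %in% (highlight %||% character()))
  ggplot2::ggplot(ranked, ggplot2::aes(x = .data$rank, y = .data$mean_z)) +
    ggplot2::geom_point(size = 0.6, colour = "grey60") +
    ggplot2::geom_point(
      data = dplyr::filter(ranked, .data$highlighted),
      colour = "firebrick", size = 1.4
    ) +
    ggplot2::labs(x = "rank (1 = most immune-resistant)", y = "mean z") +
    ggplot2::theme_minimal()
}
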