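# Signature derivation: per-dataset stemness-correlated genes (Gx),
# malignant-upregulated genes (Gy), their intersection (Gn), and a
# cross-dataset geometric-mean aggregation into the final stemness
# signature.

# Vectorized Spearman of each column of x against y: average-rank ties,
# p-values from the t-approximation (df = n - 2).
spearman_cols <- function(x, y) {
  n <- length(y)
  rx <- apply(x, 2, rank, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  r <- suppressWarnings(as.vector(cor(rx, ry)))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-15] <- 0
  list(r = r, p = p)
}

#' Stemness-correlated genes (Gx) in one dataset
#'
#' Spearman-correlates each gene's expression with the per-cell stemness
#' score over malignant cells. A gene passes when its correlation is
#' positive and the within-dataset Benjamini-Hochberg FDR is below
#' `fdr_cutoff`. Genes expressed (value > 0) in fewer than `min_cells`
#' cells are skipped (`NA` statistics, `pass = FALSE`) and their count is
#' logged.
#'
#' @param cells An [expr_mat()], cells x genes, malignant cells only
#'   (lognorm layer; raw counts are normalized internally).
#' @param scores A `stemness_result` from [stemness_score()], aligned on
#'   cell ids.
#' @param fdr_cutoff FDR threshold (default 1e-5).
#' @param min_cells Minimum number of expressing cells for a gene to be
#'   tested (default 3).
#' @return A `gx_table` tibble: `gene`, `spearman_r`, `p_value`, `fdr`,
#'   `n_expressing`, `pass`.
#' @export
compute_gx <- function(cells, scores, fdr_cutoff = 1e-5, min_cells = 3) {
  stopifnot(inherits(cells, "expr_mat"), inherits(scores, "stemness_result"))
  if (cells$orientation != "cell_by_gene") {
    stop("compute_gx expects a cell_by_gene matrix", call. = FALSE)
  }
  if (nrow(cells$values) < 10) {
    stop("compute_gx requires at least 10 cells", call. = FALSE)
  }
  if (!identical(rownames(cells$values), scores$cell_id)) {
    stop("cells and scores are not aligned on cell ids", call. = FALSE)
  }
  x <- em_values(lognormalize(cells))
  n_expr <- colSums(x > 0)
  testable <- n_expr >= min_cells
  if (any(!testable)) {
    ss_log("compute_gx: %d genes expressed in < %d cells skipped",
           sum(!testable), min_cells)
  }
  r <- p <- rep(NA_real_, ncol(x))
  if (any(testable)) {
    sp <- spearman_cols(x[, testable, drop = FALSE], scores$score)
    r[testable] <- sp$r
    p[testable] <- sp$p
  }
  fdr <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  fdr[ok] <- p.adjust(p[ok], method = "BH")
  structure(
    tibble::tibble(
      gene = colnames(x),
      spearman_r = r,
      p_value = p,
      fdr = fdr,
      n_expressing = as.integer(n_expr),
      pass = !is.na(r) & r > 0 & !is.na(fdr) & fdr < fdr_cutoff
    ),
    class = c("gx_table", "tbl_df", "tbl", "data.frame")
  )
}

# Vectorized two-sided Wilcoxon rank-sum with tie-corrected normal
# approximation (no continuity correction). x: cells x genes; g1: logical
# group-1 membership.
wilcox_cols <- function(x, g1) {
  n <- nrow(x)
  n1 <- sum(g1)
  n2 <- n - n1
  w1 <- numeric(ncol(x))
  tie_term <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    xj <- x[, j]
    rj <- rank(xj, ties.method = "average")
    w1[j] <- sum(rj[g1])
    tsz <- tabulate(match(xj, unique(xj)))
    tie_term[j] <- sum(tsz^3 - tsz)
  }
  mu <- n1 * (n + 1) / 2
  v <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- ifelse(v > 0, (w1 - mu) / sqrt(v), 0)
  p <- ifelse(v > 0, 2 * pnorm(-abs(z)), 1)
  list(statistic = w1 - n1 * (n1 + 1) / 2, z = z, p = p)
}

#' Malignant-upregulated genes (Gy) in one dataset
#'
#' Differential expression of malignant versus non-malignant cells on the
#' log-normalized layer. The fold change is computed on the linear scale
#' with a +1 pseudocount, `logfc = ln((mean(expm1(x_mal)) + 1) /
#' (mean(expm1(x_other)) + 1))`, and significance from a two-sided Wilcoxon
#' rank-sum test (tie-corrected normal approximation) with within-dataset
#' BH-FDR. A gene passes when `logfc >= lfc_cutoff` and `fdr < fdr_cutoff`.
#'
#' @param cells An [expr_mat()], cells x genes, all cells (raw counts are
#'   normalized internally).
#' @param malignant Logical vector aligned with the rows of `cells`.
#' @param lfc_cutoff Natural-log fold-change threshold (default 0.25).
#' @param fdr_cutoff FDR threshold (default 1e-5).
#' @return A `gy_table` tibble: `gene`, `logfc`, `p_value`, `fdr`, `pass`.
#' @export
compute_gy <- function(cells, malignant, lfc_cutoff = 0.25,
                       fdr_cutoff = 1e-5) {
  stopifnot(inherits(cells, "expr_mat"))
  if (cells$orientation != "cell_by_gene") {
    stop("compute_gy expects a cell_by_gene matrix", call. = FALSE)
  }
  malignant <- as.logical(malignant)
  if (length(malignant) != nrow(cells$values)) {
    stop("malignant flags not aligned with cells", call. = FALSE)
  }
  if (sum(malignant) < 3 || sum(!malignant) < 3) {
    stop("each group needs at least 3 cells", call. = FALSE)
  }
  x <- em_values(lognormalize(cells))
  lin <- expm1(x)
  logfc <- log((colMeans(lin[malignant, , drop = FALSE]) + 1) /
                 (colMeans(lin[!malignant, , drop = FALSE]) + 1))
  wt <- wilcox_cols(x, malignant)
  fdr <- p.adjust(wt$p, method = "BH")
  structure(
    tibble::tibble(
      gene = colnames(x),
      logfc = unname(logfc),
      p_value = wt$p,
      fdr = fdr,
      pass = logfc >= lfc_cutoff & fdr < fdr_cutoff
    ),
    class = c("gy_table", "tbl_df", "tbl", "data.frame")
  )
}

#' Intersect Gx and Gy passers (Gn)
#'
#' Genes tested in one table but absent from the other count as failing the
#' missing filter.
#'
#' @param gx A `gx_table` from [compute_gx()].
#' @param gy A `gy_table` from [compute_gy()] on the same dataset.
#' @return Sorted character vector of genes passing both filters.
#' @export
derive_gn <- function(gx, gy) {
  sort(intersect(gx$gene[gx$pass], gy$gene[gy$pass]))
}

#' Aggregate per-dataset Gn gene sets into a signature
#'
#' For each gene appearing in at least one dataset's Gn, the geometric mean
#' of its stemness correlations is taken over the datasets where it
#' qualified (datasets where the gene is absent from Gn contribute
#' nothing). Genes with geometric mean strictly above `threshold` and at
#' least `min_datasets` qualifying datasets form the signature. Gx
#' guarantees every contributing correlation is positive; a non-positive
#' contribution is an internal-consistency error.
#'
#' @param contributions A list with one tibble per dataset, each with
#'   columns `gene` and `spearman_r` restricted to that dataset's Gn (see
#'   [gn_contributions()]).
#' @param threshold Geometric-mean cutoff, exclusive (default 0.4).
#' @param min_datasets Minimum number of qualifying datasets (default 1).
#' @return A tibble: `gene`, `geometric_mean_r`, `n_datasets`,
#'   `in_signature`, sorted by decreasing geometric mean.
#' @export
aggregate_signature <- function(contributions, threshold = 0.4,
                                min_datasets = 1) {
  stopifnot(length(contributions) >= 1)
  all_r <- dplyr::bind_rows(contributions)
  if (nrow(all_r) == 0) {
    return(tibble::tibble(gene = character(), geometric_mean_r = numeric(),
                          n_datasets = integer(), in_signature = logical()))
  }
  if (any(all_r$spearman_r <= 0)) {
    stop("internal consistency error: a Gn gene contributed a non-positive correlation",
         call. = FALSE)
  }
  out <- all_r |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      geometric_mean_r = exp(mean(log(.data$spearman_r))),
      n_datasets = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      in_signature = .data$geometric_mean_r > threshold &
        .data$n_datasets >= min_datasets
    ) |>
    dplyr::arrange(dplyr::desc(.data$geometric_mean_r))
  out
}

#' Gn contributions of one dataset
#'
#' The `(gene, spearman_r)` rows a dataset feeds into
#' [aggregate_signature()]: its Gx correlations restricted to Gn.
#'
#' @param gx,gy Tables from [compute_gx()] / [compute_gy()].
#' @return A tibble with columns `gene`, `spearman_r`.
#' @export
gn_contributions <- function(gx, gy) {
  gn <- derive_gn(gx, gy)
  dplyr::filter(
    dplyr::select(gx, "gene", "spearman_r"),
    .data$gene %in% gn
  )
}

#' Derive a stemness signature from a single-cell panel
#'
#' Runs the full derivation on each dataset — stemness scoring on malignant
#' cells, Gx (stemness-correlated), Gy (malignant-upregulated), their
#' intersection Gn — then aggregates across datasets by geometric-mean
#' correlation (see [aggregate_signature()]).
#'
#' @param panel A list of datasets as produced by [simulate_scrna_panel()]:
#'   each a list with `counts` (an [expr_mat()], cells x genes) and
#'   `malignant` (logical).
#' @param threshold,min_datasets Passed to [aggregate_signature()].
#' @param fdr_cutoff,lfc_cutoff Per-dataset filter thresholds.
#' @param n_top_genes Passed to [stemness_score()].
#' @return A `signature_derivation` object: `per_dataset` (list of
#'   `gx`/`gy`/`gn` per dataset), `aggregate` (tibble), `signature`
#'   (character vector), `threshold`, `min_datasets`.
#' @export
derive_signature <- function(panel, threshold = 0.4, min_datasets = 1,
                             fdr_cutoff = 1e-5, lfc_cutoff = 0.25,
                             n_top_genes = 200) {
  stopifnot(length(panel) >= 1)
  per_dataset <- lapply(panel, function(ds) {
    mal <- as.logical(ds$malignant)
    mal_cells <- expr_mat(
      em_values(ds$counts)[mal, , drop = FALSE],
      layer_tag = ds$counts$layer_tag, orientation = "cell_by_gene"
    )
    scores <- stemness_score(mal_cells, n_top_genes = n_top_genes)
    gx <- compute_gx(lognormalize(mal_cells), scores,
                     fdr_cutoff = fdr_cutoff)
    gy <- compute_gy(ds$counts, mal, lfc_cutoff = lfc_cutoff,
                     fdr_cutoff = fdr_cutoff)
    list(stemness = scores, gx = gx, gy = gy, gn = derive_gn(gx, gy))
  })
  contribs <- lapply(per_dataset, function(d) gn_contributions(d$gx, d$gy))
  agg <- aggregate_signature(contribs, threshold = threshold,
                             min_datasets = min_datasets)
  structure(
    list(
      per_dataset = per_dataset,
      aggregate = agg,
      signature = agg$gene[agg$in_signature],
      threshold = threshold,
      min_datasets = min_datasets
    ),
    class = "signature_derivation"
  )
}

#' @export
print.signature_derivation <- function(x, ...) {
  cat(sprintf(
    "<signature_derivation> %d datasets; %d signature genes (geometric mean r > %.2f)\n",
    length(x$per_dataset), length(x$signature), x$threshold
  ))
  invisible(x)
}

#' @rdname derive_signature
#' @param x A `signature_derivation`.
#' @param ... Ignored.
#' @method tidy signature_derivation
#' @export
tidy.signature_derivation <- function(x, ...) x$aggregate

#' @rdname derive_signature
#' @method glance signature_derivation
#' @export
glance.signature_derivation <- function(x, ...) {
  tibble::tibble(
    n_datasets = length(x$per_dataset),
    n_signature = length(x$signature),
    threshold = x$threshold,
    min_datasets = x$min_datasets
  )
}

#' Plot the cross-dataset aggregation of a signature derivation
#'
#' Geometric-mean correlation per candidate gene, colored by inclusion.
#'
#' @param object A `signature_derivation`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot signature_derivation
#' @export
autoplot.signature_derivation <- function(object, ...) {
  agg <- dplyr::mutate(object$aggregate,
                       rank = dplyr::row_number(dplyr::desc(.data$geometric_mean_r)))
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$rank,
                                    y = .data$geometric_mean_r,
                                    colour = .data$in_signature)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = "candidate gene rank", y = "geometric mean Spearman r",
                  colour = "in signature") +
    ggplot2::theme_minimal()
}
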