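# Gene-counts based per-cell stemness scoring.
#
# Less differentiated cells express detectably more genes; the scorer
# exploits that association: count expressed genes per cell, find the genes
# whose expression tracks that count, average them into a gene-counts
# signature (GCS), optionally smooth over a kNN cell graph, and rank-scale
# to [0, 1]. This is a transparent, testable variant of the published
# gene-counts framework (which additionally uses non-negative regression and
# Markov diffusion); higher score = higher stemness.

#' Per-cell expressed-gene counts
#'
#' Number of genes with value > 0 in each cell.
#'
#' @param cells An [expr_mat()] with `orientation = "cell_by_gene"`
#'   (raw counts or lognorm: both share the same zeros).
#' @return Named integer vector, one entry per cell.
#' @export
gene_counts <- function(cells) {
  stopifnot(inherits(cells, "expr_mat"))
  if (cells$orientation != "cell_by_gene") {
    stop("gene_counts expects a cell_by_gene matrix", call. = FALSE)
  }
  if (nrow(cells$values) == 0 || ncol(cells$values) == 0) {
    stop("empty expression matrix", call. = FALSE)
  }
  v <- cells$values
  if (inherits(v, "sparseMatrix")) {
    out <- Matrix::rowSums(v > 0)
  } else {
    out <- rowSums(v > 0)
  }
  setNames(as.integer(out), rownames(v))
}

#' Score per-cell stemness from expression
#'
#' The score is built in five steps: (1) count expressed genes per cell;
#' (2) Pearson-correlate every gene's (log-normalized) expression with that
#' count; (3) average the `n_top_genes` most-correlated genes into a
#' gene-counts signature (GCS) per cell; (4) optionally smooth the GCS over
#' a k-nearest-neighbor cell graph (Euclidean distance in top-PC space) for
#' `smoothing_iters` rounds of neighbor averaging; (5) rank-scale to
#' \[0, 1\] with average ranks for ties, so the score always spans exactly
#' 0..1 whenever at least two distinct GCS values exist. Higher score =
#' higher stemness.
#'
#' @param cells An [expr_mat()], cells x genes. Raw counts are
#'   log-normalized internally (see [lognormalize()]).
#' @param n_top_genes Number of top count-correlated genes averaged into the
#'   GCS (clamped to the number of genes, with a warning).
#' @param knn Neighbors per cell for smoothing (must be < number of cells).
#' @param smoothing_iters Rounds of kNN averaging (0 = no smoothing).
#' @param n_pcs Principal components used for the kNN graph.
#' @return A `stemness_result` tibble: `cell_id`, `gene_counts`, `gcs`,
#'   `score`.
#' @export
stemness_score <- function(cells, n_top_genes = 200, knn = 30,
                           smoothing_iters = 0, n_pcs = 30) {
  stopifnot(inherits(cells, "expr_mat"))
  if (cells$orientation != "cell_by_gene") {
    stop("stemness_score expects a cell_by_gene matrix", call. = FALSE)
  }
  n_cells <- nrow(cells$values)
  if (n_cells < 10) {
    stop("stemness_score requires at least 10 cells", call. = FALSE)
  }
  if (smoothing_iters > 0 && knn >= n_cells) {
    stop("knn must be smaller than the number of cells", call. = FALSE)
  }
  gc <- gene_counts(cells)
  x <- em_values(lognormalize(cells))

  n_genes <- ncol(x)
  if (n_top_genes > n_genes) {
    warning("n_top_genes > number of genes; clamped to ", n_genes,
            call. = FALSE)
    n_top_genes <- n_genes
  }
  r <- suppressWarnings(as.vector(cor(x, gc)))
  r[is.na(r)] <- -Inf # constant genes never make the top list
  top <- order(r, decreasing = TRUE)[seq_len(n_top_genes)]
  gcs <- rowMeans(x[, top, drop = FALSE])

  if (smoothing_iters > 0) {
    pc <- prcomp(x, rank. = min(n_pcs, n_genes, n_cells - 1),
                 center = TRUE, scale. = FALSE)$x
    dmat <- as.matrix(stats::dist(pc))
    nn <- t(apply(dmat, 1, function(dr) order(dr)[seq_len(knn + 1)]))
    for (i in seq_len(smoothing_iters)) {
      gcs <- vapply(seq_len(n_cells),
                    function(ci) mean(gcs[nn[ci, ]]), numeric(1))
    }
    names(gcs) <- rownames(x)
  }

  score <- rank_scale_01(gcs)
  structure(
    tibble::tibble(
      cell_id = rownames(x),
      gene_counts = as.integer(gc),
      gcs = unname(gcs),
      score = unname(score)
    ),
    class = c("stemness_result", "tbl_df", "tbl", "data.frame")
  )
}

# rank -> [0, 1]; average ranks for ties; all-equal input maps to 0.5
rank_scale_01 <- function(x) {
  r <- rank(x, ties.method = "average")
  if (max(r) == min(r)) {
    return(setNames(rep(0.5, length(x)), names(x)))
  }
  setNames((r - min(r)) / (max(r) - min(r)), names(x))
}

#' @export
print.stemness_result <- function(x, ...) {
  cat(sprintf("<stemness_result> %d cells; score in [%.2f, %.2f]\n",
              nrow(x), min(x$score), max(x$score)))
  NextMethod()
}

#' Plot a stemness score distribution
#'
#' Score versus expressed-gene count, the association the scorer exploits.
#'
#' @param object A `stemness_result`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot stemness_result
#' @export
autoplot.stemness_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$gene_counts,
                                       y = .data$score)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "expressed genes per cell", y = "stemness score") +
    ggplot2::theme_minimal()
}
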