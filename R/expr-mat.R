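#' Expression matrix container
#'
#' A light wrapper around a dense or sparse numeric matrix that records two
#' things readers are otherwise left to guess: the orientation (bulk matrices
#' are gene x sample, single-cell matrices cell x gene) and the expression
#' layer (`raw_counts`, `lognorm`, or `tpm_like`). Row and column identifiers
#' live in `dimnames` and must be unique.
#'
#' @param values Numeric matrix (base `matrix` or a `Matrix` sparse class)
#'   with row and column names.
#' @param layer_tag One of `"raw_counts"`, `"lognorm"`, `"tpm_like"`.
#' @param orientation One of `"gene_by_sample"` (bulk) or `"cell_by_gene"`
#'   (single-cell).
#' @return An object of class `expr_mat`.
#' @export
expr_mat <- function(values,
                     layer_tag = c("raw_counts", "lognorm", "tpm_like"),
                     orientation = c("gene_by_sample", "cell_by_gene")) {
  layer_tag <- match.arg(layer_tag)
  orientation <- match.arg(orientation)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs row and column identifiers", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate row identifiers in expression matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate column identifiers in expression matrix", call. = FALSE)
  }
  vals <- if (inherits(values, "sparseMatrix")) values@x else values
  if (any(!is.finite(vals))) {
    stop("expression values must be finite", call. = FALSE)
  }
  if (layer_tag == "raw_counts" && any(vals < 0)) {
    stop("raw_counts layer must be non-negative", call. = FALSE)
  }
  structure(
    list(values = values, layer_tag = layer_tag, orientation = orientation),
    class = "expr_mat"
  )
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf(
    "<expr_mat> %d x %d [%s, %s]\n",
    nrow(x$values), ncol(x$values), x$orientation, x$layer_tag
  ))
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' Log-normalize raw counts
#'
#' Scales each cell (or sample) to a fixed total of `scale_factor` counts and
#' applies `log1p`, the dominant single-cell convention. For `cell_by_gene`
#' matrices rows are rescaled; for `gene_by_sample`, columns. A matrix already
#' tagged `lognorm` is returned unchanged.
#'
#' @param x An [expr_mat()].
#' @param scale_factor Target library size before `log1p` (default 10000).
#' @return An `expr_mat` with `layer_tag = "lognorm"`.
#' @export
lognormalize <- function(x, scale_factor = 1e4) {
  stopifnot(inherits(x, "expr_mat"))
  if (x$layer_tag == "lognorm") {
    return(x)
  }
  v <- as.matrix(x$values)
  if (x$orientation == "cell_by_gene") {
    tot <- rowSums(v)
    tot[tot == 0] <- 1
    v <- log1p(v / tot * scale_factor)
  } else {
    tot <- colSums(v)
    tot[tot == 0] <- 1
    v <- log1p(sweep(v, 2, tot, "/") * scale_factor)
  }
  expr_mat(v, layer_tag = "lognorm", orientation = x$orientation)
}

# internal: dense numeric matrix out of an expr_mat
em_values <- function(x) as.matrix(x$values)
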