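#' @importFrom rlang .data
#' @importFrom stats median sd setNames rnorm runif rbinom rexp rnbinom rlnorm
#'   cor quantile pt pnorm phyper p.adjust prcomp dnorm rank wilcox.test
#'   fisher.test ecdf var
#' @importFrom utils head
NULL

# Minimal stderr logger. Levels: debug < info < warn. The threshold is the
# option `stemsig.log_level` (default "info").
ss_log <- function(msg, ..., level = "info") {
  levels <- c(debug = 1, info = 2, warn = 3)
  thr <- getOption("stemsig.log_level", "info")
  if (levels[[level]] >= levels[[thr]]) {
    message(sprintf("[stemsig:%s] %s", level, sprintf(msg, ...)))
  }
  invisible(NULL)
}

#' Read a MatrixMarket triplet with gene/barcode sidecars
#'
#' Loads a sparse single-cell count matrix stored as a MatrixMarket
#' coordinate file with one-identifier-per-line sidecars, the layout 10x-style
#' pipelines emit (genes as rows, cells as columns). Sparsity is preserved.
#' Duplicate gene symbols are disambiguated by suffixing (`.1`, `.2`, ...)
#' and the event is logged.
#'
#' @param matrix_path Path to the `.mtx` coordinate file.
#' @param genes_path Path to the gene-identifier sidecar (one per line,
#'   matching the matrix rows).
#' @param barcodes_path Path to the cell-barcode sidecar (one per line,
#'   matching the matrix columns).
#' @return An [expr_mat()] with `layer_tag = "raw_counts"`; genes are rows.
#' @export
read_mtx_triplet <- function(matrix_path, genes_path, barcodes_path) {
  m <- Matrix::readMM(matrix_path)
  genes <- readLines(genes_path)
  barcodes <- readLines(barcodes_path)
  if (length(genes) != nrow(m) || length(barcodes) != ncol(m)) {
    stop(sprintf(
      "dimension mismatch: %s declares %d x %d but %s has %d genes and %s has %d barcodes",
      matrix_path, nrow(m), ncol(m), genes_path, length(genes),
      barcodes_path, length(barcodes)
    ), call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    n_dup <- sum(duplicated(genes))
    genes <- make.unique(genes, sep = ".")
    ss_log("disambiguated %d duplicate gene symbols by suffixing", n_dup)
  }
  if (anyDuplicated(barcodes)) {
    stop("duplicate cell barcodes in ", barcodes_path, call. = FALSE)
  }
  dimnames(m) <- list(genes, barcodes)
  expr_mat(m, layer_tag = "raw_counts", orientation = "gene_by_sample")
}

#' Write a sparse matrix as a MatrixMarket triplet
#'
#' Inverse of [read_mtx_triplet()]; the reader is total on this writer's
#' output.
#'
#' @param x An [expr_mat()] (genes as rows).
#' @param matrix_path,genes_path,barcodes_path Output paths.
#' @return Invisibly, the matrix path.
#' @export
write_mtx_triplet <- function(x, matrix_path, genes_path, barcodes_path) {
  stopifnot(inherits(x, "expr_mat"))
  m <- methods::as(methods::as(Matrix::Matrix(x$values, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, matrix_path)
  writeLines(rownames(x$values), genes_path)
  writeLines(colnames(x$values), barcodes_path)
  invisible(matrix_path)
}

#' Read gene sets from a GMT file
#'
#' Tab-separated lines `name<TAB>description<TAB>member...`. Member order is
#' preserved; duplicate members within a set are dropped with a warning.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors, one per set.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has fewer than 3 fields", i), call. = FALSE)
    }
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      warning(sprintf(
        "set '%s' (line %d): %d duplicate members removed",
        fields[[1]], i, sum(duplicated(members))
      ), call. = FALSE)
      members <- unique(members)
    }
    nms[[i]] <- fields[[1]]
    sets[[i]] <- members
  }
  setNames(sets, nms)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to the set names).
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[[i]], descriptions[[i]], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical table
#'
#' Reads a TSV with at least a `sample_id` column and derives the binary
#' response label from RECIST best overall response: complete (CR) and
#' partial (PR) responses are responders; stable (SD) and progressive (PD)
#' disease are non-responders. Missing optional columns (`response_raw`,
#' `os_time`, `os_event`, `tmb`, `batch`) are filled with `NA` and logged.
#'
#' @param path Path to a tab-separated clinical table.
#' @return A tibble with columns `sample_id`, `response_raw`,
#'   `response_binary`, `os_time`, `os_event`, `tmb`, `batch`.
#' @export
read_clinical <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(tab)) {
    stop("clinical table must have a sample_id column", call. = FALSE)
  }
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicate sample_id in clinical table", call. = FALSE)
  }
  optional <- c(response_raw = "character", os_time = "double",
                os_event = "double", tmb = "double", batch = "character")
  for (col in names(optional)) {
    if (!col %in% names(tab)) {
      tab[[col]] <- vector(optional[[col]], nrow(tab))
      tab[[col]][] <- NA
      ss_log("clinical column '%s' missing; filled with NA", col)
    }
  }
  if (any(!is.na(tab$os_time) & tab$os_time < 0)) {
    stop("os_time must be non-negative", call. = FALSE)
  }
  tab$response_binary <- response_to_binary(tab$response_raw)
  dplyr::select(
    tab, "sample_id", "response_raw", "response_binary",
    "os_time", "os_event", "tmb", "batch", dplyr::everything()
  )
}

#' Map RECIST best overall response to responder / non-responder
#'
#' @param response_raw Character vector with values in CR/PR/SD/PD (or NA).
#' @return Character vector: `"responder"` for CR/PR, `"non_responder"` for
#'   SD/PD, `NA` otherwise.
#' @export
response_to_binary <- function(response_raw) {
  out <- rep(NA_character_, length(response_raw))
  out[response_raw %in% c("CR", "PR")] <- "responder"
  out[response_raw %in% c("SD", "PD")] <- "non_responder"
  bad <- !is.na(response_raw) & !response_raw %in% c("CR", "PR", "SD", "PD")
  if (any(bad)) {
    warning(sum(bad), " unrecognized response values set to NA", call. = FALSE)
  }
  out
}

#' Read a dense expression matrix from TSV
#'
#' First column = gene (or cell) identifiers, remaining columns samples.
#'
#' @param path Path to TSV.
#' @param layer_tag,orientation Passed to [expr_mat()].
#' @return An [expr_mat()].
#' @export
read_matrix_tsv <- function(path, layer_tag = "lognorm",
                            orientation = "gene_by_sample") {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  expr_mat(m, layer_tag = layer_tag, orientation = orientation)
}

#' Write an expression matrix to TSV
#'
#' @param x An [expr_mat()].
#' @param path Output path.
#' @param id_col Name of the identifier column (default `"gene"`).
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(x, path, id_col = "gene") {
  stopifnot(inherits(x, "expr_mat"))
  tab <- tibble::as_tibble(as.matrix(x$values), rownames = id_col)
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read a panel configuration (YAML)
#'
#' A panel config lists, per single-cell dataset, the paths needed to run the
#' signature derivation: `matrix`, `genes`, `barcodes`, and `malignant`
#' (a one-flag-per-cell sidecar of 0/1).
#'
#' @param path Path to a YAML file with a top-level `datasets` list.
#' @return A tibble with one row per dataset.
#' @export
read_panel_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$datasets) || !length(cfg$datasets)) {
    stop("panel config must have a non-empty 'datasets' list", call. = FALSE)
  }
  required <- c("matrix", "genes", "barcodes", "malignant")
  purrr::map_dfr(cfg$datasets, function(d) {
    missing <- setdiff(required, names(d))
    if (length(missing)) {
      stop("panel config dataset missing fields: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    tibble::as_tibble(d[unique(c("name", required))[
      unique(c("name", required)) %in% names(d)]])
  })
}
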