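# End-to-end response-model workflow: batch correction, cohort splitting,
# kernel Naive Bayes training, and ROC evaluation on held-out samples.

#' Run the full ICI response-model workflow on one cohort table
#'
#' Combines the response-model steps the way the analysis is meant to be
#' run: batch-correct the expression matrix across cohorts, restrict to the
#' signature genes, carve out an independent test fraction and a validation
#' fraction, train the (kernel) Naive Bayes classifier on the remainder,
#' and evaluate AUC on the held-out sets.
#'
#' @param expr An [expr_mat()], genes x samples.
#' @param clinical Tibble with `sample_id`, `response_binary` and,
#'   when `correct_batch = TRUE`, `batch` (see [read_clinical()]).
#'   Samples with `NA` response are dropped with a log line.
#' @param signature_genes Character vector; features are the intersection
#'   with the matrix's genes.
#' @param val_fraction Fraction of the non-test samples held out for
#'   validation (default 0.2).
#' @param test_fraction Fraction of all samples carved out first as an
#'   independent test set (default 0 = none).
#' @param seed Integer seed driving both splits.
#' @param correct_batch Run [batch_correct()] first (default `TRUE`).
#' @param use_kernel,laplace_fl,bandwidth_adjust Passed to [train_nb()].
#' @return A `response_pipeline` list: `model`, `ids` (train / validation /
#'   test), `predictions` (tibble with split labels), `roc_val`, `roc_test`
#'   (`NULL` without a test set), `features`.
#' @export
response_pipeline <- function(expr, clinical, signature_genes,
                              val_fraction = 0.2, test_fraction = 0,
                              seed = 1L, correct_batch = TRUE,
                              use_kernel = TRUE, laplace_fl = 0,
                              bandwidth_adjust = 0.75) {
  stopifnot(inherits(expr, "expr_mat"), "sample_id" %in% names(clinical),
            "response_binary" %in% names(clinical))
  keep <- !is.na(clinical$response_binary)
  if (any(!keep)) {
    ss_log("response_pipeline: %d samples without response dropped",
           sum(!keep))
  }
  clinical <- clinical[keep, ]
  if (!all(clinical$sample_id %in% colnames(expr$values))) {
    stop("clinical samples missing from the expression matrix", call. = FALSE)
  }
  expr <- expr_mat(
    em_values(expr)[, clinical$sample_id, drop = FALSE],
    layer_tag = expr$layer_tag, orientation = expr$orientation
  )
  if (correct_batch) {
    if (!"batch" %in% names(clinical)) {
      stop("batch labels required for batch correction", call. = FALSE)
    }
    expr <- batch_correct(expr, clinical$batch, allow_single = TRUE)
  }
  feats <- intersect(signature_genes, rownames(expr$values))
  if (length(feats) == 0) {
    stop("no signature genes found in the expression matrix", call. = FALSE)
  }
  x <- t(em_values(expr)[feats, clinical$sample_id, drop = FALSE])

  ids <- clinical$sample_id
  test_ids <- character(0)
  if (test_fraction > 0) {
    sp <- split_cohort(ids, val_fraction = test_fraction, seed = seed)
    test_ids <- sp$validation
    ids <- sp$train
  }
  sp <- split_cohort(ids, val_fraction = val_fraction, seed = seed + 1L)
  y <- setNames(clinical$response_binary, clinical$sample_id)

  model <- train_nb(x[sp$train, , drop = FALSE], y[sp$train],
                    use_kernel = use_kernel, laplace_fl = laplace_fl,
                    bandwidth_adjust = bandwidth_adjust)
  pred_val <- predict_response(model, x[sp$validation, , drop = FALSE])
  pred_val$split <- "validation"
  roc_val <- roc_auc(pred_val$p_responder, y[sp$validation], boot = 0)
  roc_test <- NULL
  preds <- pred_val
  if (length(test_ids)) {
    pred_test <- predict_response(model, x[test_ids, , drop = FALSE])
    pred_test$split <- "test"
    roc_test <- roc_auc(pred_test$p_responder, y[test_ids], boot = 0)
    preds <- dplyr::bind_rows(pred_val, pred_test)
  }
  structure(
    list(model = model,
         ids = list(train = sp$train, validation = sp$validation,
                    test = test_ids),
         predictions = preds, roc_val = roc_val, roc_test = roc_test,
         features = feats),
    class = "response_pipeline"
  )
}

#' @export
print.response_pipeline <- function(x, ...) {
  cat(sprintf(
    "<response_pipeline> %d features; train/val/test = %d/%d/%d; val AUC = %.3f%s\n",
    length(x$features), length(x$ids$train), length(x$ids$validation),
    length(x$ids$test), x$roc_val$auc,
    if (!is.null(x$roc_test)) sprintf("; test AUC = %.3f", x$roc_test$auc)
    else ""
  ))
  invisible(x)
}

#' @rdname response_pipeline
#' @param x A `response_pipeline` (for `glance`).
#' @param ... Ignored.
#' @method glance response_pipeline
#' @export
glance.response_pipeline <- function(x, ...) {
  tibble::tibble(
    n_train = length(x$ids$train),
    n_validation = length(x$ids$validation),
    n_test = length(x$ids$test),
    n_features = length(x$features),
    auc_validation = x$roc_val$auc,
    auc_test = if (is.null(x$roc_test)) NA_real_ else x$roc_test$auc
  )
}

#' Cross-validated grid search over the kernel bandwidth multiplier
#'
#' K-fold cross-validation of validation AUC over a grid of
#' `bandwidth_adjust` values — a small-scale stand-in for a repeated-CV
#' hyperparameter search.
#'
#' @param x Samples x features matrix.
#' @param y Two-class labels.
#' @param grid Candidate bandwidth multipliers.
#' @param k Folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return A tibble (`bandwidth_adjust`, `cv_auc`) sorted by decreasing
#'   AUC.
#' @export
tune_nb_bandwidth <- function(x, y, grid = c(0.5, 0.75, 1, 1.5), k = 5,
                              seed = 1L) {
  x <- as.matrix(x)
  y <- factor(y)
  stopifnot(nrow(x) == length(y), k >= 2)
  folds <- with_seed(seed, sample(rep(seq_len(k), length.out = nrow(x))))
  res <- purrr::map_dfr(grid, function(adj) {
    aucs <- vapply(seq_len(k), function(f) {
      tr <- folds != f
      if (nlevels(droplevels(y[tr])) < 2 ||
          nlevels(droplevels(y[!tr])) < 2) {
        return(NA_real_)
      }
      m <- train_nb(x[tr, , drop = FALSE], y[tr],
                    bandwidth_adjust = adj)
      p <- predict_response(m, x[!tr, , drop = FALSE])
      roc_auc(p$p_responder, y[!tr] == m$positive, boot = 0)$auc
    }, numeric(1))
    tibble::tibble(bandwidth_adjust = adj, cv_auc = mean(aucs, na.rm = TRUE))
  })
  dplyr::arrange(res, dplyr::desc(.data$cv_auc))
}
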