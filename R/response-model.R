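# Immunotherapy response classification: batch correction across cohorts,
# train/validation splitting, a kernel Naive Bayes classifier on signature
# genes, and ROC evaluation.

#' Batch-correct a bulk expression matrix
#'
#' Location-scale batch adjustment with empirical-Bayes shrinkage of
#' per-batch per-gene means and variances toward cohort-level priors
#' (parametric form, no covariates), via `sva::ComBat`. Genes with zero
#' variance inside some batch cannot be scale-adjusted; they are corrected
#' by location only (batch mean removed, grand mean restored) and the event
#' is logged.
#'
#' @param bulk An [expr_mat()], genes x samples.
#' @param batch Character/factor batch label per sample.
#' @param allow_single If `TRUE`, a single batch passes through unchanged
#'   instead of erroring.
#' @return An [expr_mat()] with the same dimensions and `layer_tag`.
#' @export
batch_correct <- function(bulk, batch, allow_single = FALSE) {
  stopifnot(inherits(bulk, "expr_mat"))
  if (bulk$orientation != "gene_by_sample") {
    stop("batch_correct expects a gene_by_sample matrix", call. = FALSE)
  }
  x <- em_values(bulk)
  batch <- as.character(batch)
  stopifnot(length(batch) == ncol(x))
  tab <- table(batch)
  if (length(tab) < 2) {
    if (allow_single) {
      return(bulk)
    }
    stop("batch_correct requires at least 2 batches (or allow_single = TRUE)",
         call. = FALSE)
  }
  if (any(tab < 3)) {
    stop("every batch needs at least 3 samples", call. = FALSE)
  }

  # split off genes that are constant within some batch
  batch_sds <- vapply(unique(batch), function(b) {
    apply(x[, batch == b, drop = FALSE], 1, sd)
  }, numeric(nrow(x)))
  degenerate <- apply(batch_sds, 1, function(s) any(s == 0))
  out <- x
  if (any(!degenerate)) {
    out[!degenerate, ] <- suppressMessages(
      sva::ComBat(dat = x[!degenerate, , drop = FALSE], batch = batch)
    )
  }
  if (any(degenerate)) {
    ss_log("batch_correct: %d zero-variance genes adjusted by location only",
           sum(degenerate))
    xd <- x[degenerate, , drop = FALSE]
    grand <- rowMeans(xd)
    for (b in unique(batch)) {
      sel <- batch == b
      xd[, sel] <- xd[, sel] - rowMeans(xd[, sel, drop = FALSE]) + grand
    }
    out[degenerate, ] <- xd
  }
  expr_mat(out, layer_tag = bulk$layer_tag, orientation = bulk$orientation)
}

#' Split samples into training and validation sets
#'
#' The validation set holds `floor(n * val_fraction)` samples; the split is
#' a partition and is a deterministic function of the seed. With
#' `stratify_by` supplied, the validation fraction is drawn within each
#' stratum (total size may then differ from the unstratified floor by
#' rounding).
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param val_fraction Fraction held out for validation (default 0.2).
#' @param seed Integer seed.
#' @param stratify_by Optional grouping (e.g. response label) to stratify
#'   the draw.
#' @return A list with `train` and `validation` id vectors.
#' @export
split_cohort <- function(sample_ids, val_fraction = 0.2, seed = 1L,
                         stratify_by = NULL) {
  stopifnot(val_fraction > 0, val_fraction < 1,
            !anyDuplicated(sample_ids))
  with_seed(seed, {
    if (is.null(stratify_by)) {
      n_val <- floor(length(sample_ids) * val_fraction)
      val <- sample(sample_ids, n_val)
    } else {
      stopifnot(length(stratify_by) == length(sample_ids))
      val <- unlist(lapply(split(sample_ids, stratify_by), function(ids) {
        sample(ids, floor(length(ids) * val_fraction))
      }), use.names = FALSE)
    }
    list(train = setdiff(sample_ids, val), validation = val)
  })
}

bw_silverman <- function(v, adjust, global_sd) {
  n <- length(v)
  spread <- min(sd(v), stats::IQR(v) / 1.34)
  bw <- 0.9 * spread * n^(-1 / 5) * adjust
  floor_bw <- 1e-6 * (global_sd + 1e-12)
  max(bw, floor_bw)
}

#' Train a (kernel) Naive Bayes response classifier
#'
#' Class priors are the (optionally Laplace-smoothed) class frequencies.
#' With `use_kernel = TRUE` each feature gets, per class, a one-dimensional
#' Gaussian kernel density over the training values with Silverman's
#' bandwidth `0.9 * min(sd, IQR/1.34) * n^(-1/5)` times
#' `bandwidth_adjust`; a feature with zero spread in a class receives a
#' floor bandwidth of `1e-6 * (global sd + 1e-12)`. With
#' `use_kernel = FALSE` the model degenerates to Gaussian Naive Bayes.
#' The defaults (`laplace_fl = 0`, `bandwidth_adjust = 0.75`,
#' `use_kernel = TRUE`) are the selected model's published settings.
#'
#' @param x Numeric matrix or data frame, samples x features (e.g.
#'   signature-gene expression).
#' @param y Two-class response labels (factor or character); both classes
#'   must be present and features must be complete.
#' @param use_kernel Kernel densities (`TRUE`) or Gaussian (`FALSE`).
#' @param laplace_fl Laplace pseudocount on the class priors (default 0).
#' @param bandwidth_adjust Multiplier on the Silverman bandwidth
#'   (default 0.75).
#' @param positive The class treated as "responder" in
#'   [predict_response()]; defaults to `"responder"` when present,
#'   otherwise the last factor level.
#' @return An `nb_model` object.
#' @export
train_nb <- function(x, y, use_kernel = TRUE, laplace_fl = 0,
                     bandwidth_adjust = 0.75, positive = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (any(is.na(x))) stop("features must be complete (no NA)", call. = FALSE)
  y <- factor(y)
  if (nlevels(y) != 2) {
    stop("y must contain exactly two classes", call. = FALSE)
  }
  stopifnot(nrow(x) == length(y))
  if (is.null(positive)) {
    positive <- if ("responder" %in% levels(y)) "responder" else levels(y)[2]
  }
  stopifnot(positive %in% levels(y))

  counts <- table(y)
  priors <- (counts + laplace_fl) / (sum(counts) + nlevels(y) * laplace_fl)
  global_sd <- apply(x, 2, sd)

  densities <- lapply(levels(y), function(cl) {
    xc <- x[y == cl, , drop = FALSE]
    lapply(seq_len(ncol(x)), function(j) {
      v <- xc[, j]
      if (use_kernel) {
        list(points = v, bw = bw_silverman(v, bandwidth_adjust, global_sd[j]))
      } else {
        sd_c <- sd(v)
        floor_sd <- 1e-6 * (global_sd[j] + 1e-12)
        list(mean = mean(v), sd = max(sd_c, floor_sd))
      }
    })
  })
  names(densities) <- levels(y)

  structure(
    list(
      classes = levels(y),
      positive = positive,
      priors = setNames(as.numeric(priors), levels(y)),
      features = colnames(x),
      use_kernel = use_kernel,
      laplace_fl = laplace_fl,
      bandwidth_adjust = bandwidth_adjust,
      densities = densities
    ),
    class = "nb_model"
  )
}

#' @export
print.nb_model <- function(x, ...) {
  cat(sprintf(
    "<nb_model> %s Naive Bayes; %d features; priors %s\n",
    if (x$use_kernel) "kernel" else "Gaussian", length(x$features),
    paste(sprintf("%s=%.3f", names(x$priors), x$priors), collapse = ", ")
  ))
  invisible(x)
}

nb_log_density <- function(dens, v, use_kernel) {
  if (use_kernel) {
    d <- vapply(v, function(xi) mean(dnorm(xi, dens$points, dens$bw)),
                numeric(1))
  } else {
    d <- dnorm(v, dens$mean, dens$sd)
  }
  log(pmax(d, 1e-300))
}

#' Predict responder posteriors with a Naive Bayes model
#'
#' Log-space accumulation of per-feature log-densities plus the log prior;
#' densities are floored at 1e-300 before the log. Features absent from
#' `newdata` are dropped (with a log line); with no usable features the
#' posterior equals the prior. A posterior of exactly 0.5 is labeled
#' non-responder (conservative).
#'
#' @param model An `nb_model` from [train_nb()].
#' @param newdata Samples x features matrix or data frame.
#' @return A tibble: `sample_id`, `p_responder`, `label` (`"responder"` /
#'   the other class).
#' @export
predict_response <- function(model, newdata) {
  stopifnot(inherits(model, "nb_model"))
  x <- as.matrix(newdata)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  use <- intersect(model$features, colnames(x))
  if (length(use) < length(model$features)) {
    ss_log("predict_response: %d model features absent from newdata",
           length(model$features) - length(use))
  }
  n <- nrow(x)
  loglik <- matrix(rep(log(model$priors), each = n), nrow = n,
                   dimnames = list(NULL, model$classes))
  for (f in use) {
    j <- match(f, model$features)
    for (cl in model$classes) {
      loglik[, cl] <- loglik[, cl] +
        nb_log_density(model$densities[[cl]][[j]], x[, f], model$use_kernel)
    }
  }
  mx <- apply(loglik, 1, max)
  post <- exp(loglik - mx)
  post <- post / rowSums(post)
  p_resp <- unname(post[, model$positive])
  other <- setdiff(model$classes, model$positive)
  tibble::tibble(
    sample_id = rownames(x) %||% as.character(seq_len(n)),
    p_responder = p_resp,
    label = ifelse(p_resp > 0.5, model$positive, other)
  )
}

#' @rdname train_nb
#' @param x An `nb_model` (for `tidy`/`glance`).
#' @param ... Ignored.
#' @method tidy nb_model
#' @export
tidy.nb_model <- function(x, ...) {
  purrr::map_dfr(x$classes, function(cl) {
    tibble::tibble(
      class = cl,
      feature = x$features,
      bandwidth = if (x$use_kernel)
        vapply(x$densities[[cl]], `[[`, numeric(1), "bw") else NA_real_,
      mean = if (!x$use_kernel)
        vapply(x$densities[[cl]], `[[`, numeric(1), "mean") else NA_real_,
      sd = if (!x$use_kernel)
        vapply(x$densities[[cl]], `[[`, numeric(1), "sd") else NA_real_
    )
  })
}

#' @rdname train_nb
#' @method glance nb_model
#' @export
glance.nb_model <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$features),
    use_kernel = x$use_kernel,
    laplace_fl = x$laplace_fl,
    bandwidth_adjust = x$bandwidth_adjust,
    prior_positive = x$priors[[x$positive]]
  )
}

#' Serialize / restore a Naive Bayes model as JSON
#'
#' Writes the full model — priors, feature list, and per-feature per-class
#' kernel sample points and bandwidths (or Gaussian moments) — so a
#' trained classifier can be applied elsewhere.
#'
#' @param model An `nb_model`.
#' @param path Output (input) path.
#' @return `write_nb_model`: invisibly, `path`; `read_nb_model`: an
#'   `nb_model`.
#' @export
write_nb_model <- function(model, path) {
  stopifnot(inherits(model, "nb_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_nb_model
#' @export
read_nb_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(
    list(
      classes = unlist(obj$classes),
      positive = obj$positive,
      priors = unlist(obj$priors),
      features = unname(unlist(obj$features)),
      use_kernel = isTRUE(obj$use_kernel),
      laplace_fl = obj$laplace_fl,
      bandwidth_adjust = obj$bandwidth_adjust,
      densities = lapply(obj$densities, function(cl) {
        lapply(cl, function(d) {
          lapply(d, function(v) unlist(v, use.names = FALSE))
        })
      })
    ),
    class = "nb_model"
  )
}

#' ROC curve and AUC
#'
#' AUC by the Mann-Whitney U identity (ties count one half); the curve by a
#' threshold sweep over the observed scores; a percentile-bootstrap
#' confidence interval on the AUC.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Positive/negative labels: logical, 0/1, or a factor whose
#'   level named by `positive` is the positive class.
#' @param positive Positive-class label when `labels` is not logical
#'   (default `"responder"` when present).
#' @param boot Bootstrap resamples for the AUC confidence interval
#'   (0 skips it).
#' @param conf_level Confidence level (default 0.95).
#' @return A `roc_result`: `thresholds`, `tpr`, `fpr`, `auc`, `ci`,
#'   `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, positive = NULL, boot = 1000,
                    conf_level = 0.95) {
  pos <- as_positive_logical(labels, positive)
  stopifnot(length(scores) == length(pos), !any(is.na(scores)),
            !any(is.na(pos)))
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  auc <- auc_mann_whitney(scores, pos)

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & pos) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / n0, numeric(1))

  ci <- c(NA_real_, NA_real_)
  if (boot > 0) {
    idx <- seq_along(scores)
    bs <- vapply(seq_len(boot), function(b) {
      take <- sample(idx, replace = TRUE)
      if (sum(pos[take]) == 0 || sum(!pos[take]) == 0) return(NA_real_)
      auc_mann_whitney(scores[take], pos[take])
    }, numeric(1))
    alpha <- (1 - conf_level) / 2
    ci <- unname(quantile(bs, c(alpha, 1 - alpha), na.rm = TRUE))
  }
  structure(
    list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc, ci = ci,
         n_pos = n1, n_neg = n0),
    class = "roc_result"
  )
}

auc_mann_whitney <- function(scores, pos) {
  r <- rank(scores, ties.method = "average")
  n1 <- sum(pos)
  n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_positive_logical <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels == 1)
  labels <- as.character(labels)
  if (is.null(positive)) {
    positive <- if ("responder" %in% labels) "responder" else
      sort(unique(labels))[length(unique(labels))]
  }
  labels == positive
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (%d pos / %d neg)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @rdname roc_auc
#' @param x A `roc_result`.
#' @param ... Ignored.
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) {
  tibble::tibble(threshold = x$thresholds, tpr = x$tpr, fpr = x$fpr)
}

#' @rdname roc_auc
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, ci_low = x$ci[1], ci_high = x$ci[2],
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname roc_auc
#' @param object A `roc_result`.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(tidy.roc_result(object),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}
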