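test_that("constant per-gene batch offsets are removed exactly", {
  # pure offsets, no within-batch noise: every gene takes the
  # location-only path and batch means equalize to machine precision
  genes <- sprintf("G%02d", 1:10)
  mu <- rnorm(10, 5)
  batch <- rep(c("b1", "b2"), each = 6)
  x <- matrix(mu, 10, 12, dimnames = list(genes, sprintf("s%02d", 1:12)))
  offset <- rnorm(10, 0, 2)
  x[, batch == "b2"] <- x[, batch == "b2"] + offset
  em <- expr_mat(x, "lognorm", "gene_by_sample")
  xc <- as.matrix(batch_correct(em, batch)$values)
  m1 <- rowMeans(xc[, batch == "b1"])
  m2 <- rowMeans(xc[, batch == "b2"])
  expect_lt(max(abs(m1 - m2)), 1e-6)
})

test_that("batch correction shrinks noisy batch offsets and preserves in-batch order", {
  withr::local_seed(301)
  genes <- sprintf("G%02d", 1:30)
  batch <- rep(c("b1", "b2", "b3"), each = 20)
  x <- matrix(rnorm(30 * 60, 5), 30, 60,
              dimnames = list(genes, sprintf("s%02d", 1:60)))
  for (b in unique(batch)) {
    x[, batch == b] <- x[, batch == b] + rnorm(30, 0, 2)
  }
  em <- expr_mat(x, "lognorm", "gene_by_sample")
  xc <- as.matrix(batch_correct(em, batch)$values)
  # per-gene cross-batch mean spread collapses
  spread <- function(m) {
    mean(apply(vapply(unique(batch), function(b) {
      rowMeans(m[, batch == b, drop = FALSE])
    }, numeric(30)), 1, sd))
  }
  expect_lt(spread(xc), spread(x) / 3)
  # affine within-batch adjustment keeps each gene's sample ordering
  for (b in unique(batch)) {
    for (g in sample(genes, 5)) {
      expect_equal(order(xc[g, batch == b]), order(x[g, batch == b]))
    }
  }
})

test_that("single-batch input passes through only when allowed", {
  m <- matrix(rnorm(20, 5), 4, 5,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  em <- expr_mat(m, "lognorm", "gene_by_sample")
  expect_error(batch_correct(em, rep("b1", 5)), "at least 2")
  expect_identical(batch_correct(em, rep("b1", 5), allow_single = TRUE)$values,
                   em$values)
})

test_that("cohort splitting reproduces the 80/20 arithmetic and is deterministic", {
  ids <- sprintf("p%04d", 1:772)
  sp <- split_cohort(ids, val_fraction = 0.2, seed = 7)
  expect_length(sp$train, 618)
  expect_length(sp$validation, 154)
  expect_setequal(c(sp$train, sp$validation), ids)

  sp10 <- split_cohort(sprintf("p%02d", 1:10), 0.2, seed = 1)
  expect_length(sp10$train, 8)
  expect_length(sp10$validation, 2)

  expect_identical(split_cohort(ids, 0.2, seed = 7), sp)
  expect_false(identical(split_cohort(ids, 0.2, seed = 8)$validation,
                         sp$validation))
})

test_that("stratified splits hold out the fraction within each stratum", {
  ids <- sprintf("p%03d", 1:100)
  strat <- rep(c("R", "NR"), c(40, 60))
  sp <- split_cohort(ids, 0.2, seed = 2, stratify_by = strat)
  expect_length(sp$validation, 8 + 12)
  expect_equal(sum(sp$validation %in% ids[1:40]), 8)
})

test_that("a separable single feature yields near-certain posteriors", {
  x <- matrix(c(0, 0, 0, 10, 10, 10), ncol = 1)
  y <- rep(c("A", "B"), each = 3)
  m <- train_nb(x, y, positive = "B")
  p <- predict_response(m, matrix(0, 1, 1))
  expect_lt(p$p_responder, 0.001) # posterior for A > 0.999
  expect_equal(p$label, "A")
})

test_that("the Gaussian degenerate form matches the closed-form Bayes rule", {
  withr::local_seed(311)
  n <- 100
  y <- rep(c("A", "B"), each = n / 2)
  x <- cbind(f1 = rnorm(n, ifelse(y == "B", 1, -1), 1),
             f2 = rnorm(n, ifelse(y == "B", 0.5, 0), 2))
  m <- train_nb(x, y, use_kernel = FALSE, positive = "B")
  new <- cbind(f1 = rnorm(10), f2 = rnorm(10))
  p <- predict_response(m, new)

  # closed form with the same fitted class-conditional Gaussians
  mu <- function(cl, j) mean(x[y == cl, j])
  sg <- function(cl, j) sd(x[y == cl, j])
  lik <- function(cl) {
    dnorm(new[, 1], mu(cl, 1), sg(cl, 1)) *
      dnorm(new[, 2], mu(cl, 2), sg(cl, 2)) * 0.5
  }
  oracle <- lik("B") / (lik("A") + lik("B"))
  expect_equal(p$p_responder, unname(oracle), tolerance = 1e-6)
})

test_that("kernel posteriors match a direct density-product oracle", {
  withr::local_seed(321)
  n <- 30
  y <- rep(c("A", "B"), each = n / 2)
  x <- matrix(rnorm(n * 3, ifelse(y == "B", 1, 0)), n, 3,
              dimnames = list(NULL, paste0("f", 1:3)))
  m <- train_nb(x, y, positive = "B", bandwidth_adjust = 0.75)
  new <- matrix(rnorm(6 * 3), 6, 3, dimnames = list(NULL, paste0("f", 1:3)))
  p <- predict_response(m, new)

  kd <- function(v, pts, bw) {
    vapply(v, function(xi) mean(dnorm(xi, pts, bw)), numeric(1))
  }
  lik <- function(cl) {
    out <- rep(m$priors[[cl]], 6)
    for (j in 1:3) {
      d <- m$densities[[cl]][[j]]
      out <- out * kd(new[, j], x[y == cl, j], d$bw)
    }
    out
  }
  oracle <- lik("B") / (lik("A") + lik("B"))
  expect_equal(p$p_responder, unname(oracle), tolerance = 1e-12)
})

test_that("duplicating the training set barely moves kernel posteriors", {
  withr::local_seed(331)
  n <- 60
  y <- rep(c("A", "B"), each = n / 2)
  x <- matrix(rnorm(n * 2, ifelse(y == "B", 0.8, 0)), n, 2,
              dimnames = list(NULL, c("f1", "f2")))
  new <- matrix(rnorm(20 * 2), 20, 2, dimnames = list(NULL, c("f1", "f2")))
  p1 <- predict_response(train_nb(x, y, positive = "B"), new)
  # the Silverman bandwidth shrinks as n^(-1/5), so duplication is not an
  # exact invariance; the KDE shape and priors are unchanged
  p2 <- predict_response(train_nb(rbind(x, x), c(y, y), positive = "B"), new)
  expect_lt(max(abs(p1$p_responder - p2$p_responder)), 0.05)
})

test_that("with no usable features the posterior equals the prior", {
  x <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- rep(c("A", "B"), 3)
  m <- train_nb(x, y, positive = "B", laplace_fl = 0)
  new <- matrix(0, 2, 1, dimnames = list(NULL, "unrelated"))
  p <- predict_response(m, new)
  expect_equal(p$p_responder, rep(m$priors[["B"]], 2))
})

test_that("a symmetric two-class problem gives posterior one half at the midpoint", {
  x <- matrix(c(-3, -1, 1, 3), ncol = 1, dimnames = list(NULL, "f"))
  y <- c("A", "A", "B", "B")
  m <- train_nb(x, y, positive = "B")
  p <- predict_response(m, matrix(0, 1, 1, dimnames = list(NULL, "f")))
  expect_equal(p$p_responder, 0.5, tolerance = 1e-12)
  # exactly 0.5 labels as the non-positive class (conservative)
  expect_equal(p$label, "A")
})

test_that("train_nb rejects degenerate inputs", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(train_nb(x, rep("A", 5)), "two classes")
  x[1] <- NA
  expect_error(train_nb(x, c("A", "A", "B", "B", "B")), "NA")
})

test_that("AUC matches the pairwise oracle and its known extremes", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1), boot = 0)$auc, 1)
  expect_equal(roc_auc(rep(2, 8), rep(c(0, 1), 4), boot = 0)$auc, 0.5)

  withr::local_seed(341)
  for (i in 1:5) {
    sc <- sample(1:6, 40, replace = TRUE) # plenty of ties
    lab <- rbinom(40, 1, 0.4)
    if (sum(lab) == 0 || sum(lab) == 40) next
    r <- roc_auc(sc, lab, boot = 0)
    expect_equal(r$auc, oracle_auc_pairs(sc, lab == 1), tolerance = 1e-12)
  }
})

test_that("the ROC curve is monotone and AUC is rank-invariant", {
  withr::local_seed(351)
  sc <- rnorm(60)
  lab <- rbinom(60, 1, 0.5)
  r <- roc_auc(sc, lab, boot = 50)
  expect_true(all(diff(r$tpr) >= 0))
  expect_true(all(diff(r$fpr) >= 0))
  expect_equal(utils::tail(r$tpr, 1), 1)
  expect_equal(utils::tail(r$fpr, 1), 1)
  # strictly increasing transform leaves the AUC unchanged
  r2 <- roc_auc(exp(2 * sc + 1), lab, boot = 0)
  expect_equal(r2$auc, r$auc)
  # trapezoidal area under the threshold-sweep curve equals the U statistic
  area <- sum(diff(r$fpr) * (utils::head(r$tpr, -1) + utils::tail(r$tpr, -1)) / 2)
  expect_equal(area, r$auc, tolerance = 1e-12)
})

test_that("a kernel NB model round-trips through JSON with identical predictions", {
  withr::local_seed(361)
  n <- 40
  y <- rep(c("responder", "non_responder"), each = n / 2)
  x <- matrix(rnorm(n * 3, ifelse(y == "responder", 0, 1)), n, 3,
              dimnames = list(NULL, paste0("g", 1:3)))
  m <- train_nb(x, y)
  path <- withr::local_tempfile(fileext = ".json")
  write_nb_model(m, path)
  m2 <- read_nb_model(path)
  new <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, paste0("g", 1:3)))
  expect_equal(predict_response(m2, new), predict_response(m, new))

  g <- train_nb(x, y, use_kernel = FALSE)
  write_nb_model(g, path)
  expect_equal(predict_response(read_nb_model(path), new),
               predict_response(g, new))
})
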