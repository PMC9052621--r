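test_that("Gx flags genes tracking the stemness score and matches the rank oracle", {
  withr::local_seed(101)
  n <- 60
  score <- runif(n)
  m <- matrix(rexp(n * 20), n, 20)
  m[, 1] <- score          # perfectly correlated
  m[, 2] <- 1 - score + 0.001 # perfectly anti-correlated, still "expressed"
  em <- toy_cells(m, layer = "lognorm")
  sc <- as_stemness(rownames(em$values), score)
  gx <- compute_gx(em, sc)
  expect_equal(gx$spearman_r[1], 1)
  expect_true(gx$pass[1])
  expect_equal(gx$spearman_r[2], -1)
  expect_false(gx$pass[2])

  # brute-force rank-then-Pearson oracle on a 30-cell random dataset
  n2 <- 30
  m2 <- matrix(sample(0:6, n2 * 15, replace = TRUE), n2, 15)
  em2 <- toy_cells(m2, layer = "lognorm")
  sc2 <- as_stemness(rownames(em2$values), rnorm(n2))
  gx2 <- compute_gx(em2, sc2)
  for (j in seq_len(15)) {
    if (is.na(gx2$spearman_r[j])) next
    o <- oracle_spearman(m2[, j], sc2$score)
    expect_equal(gx2$spearman_r[j], o$r, tolerance = 1e-12)
    expect_equal(gx2$p_value[j], o$p, tolerance = 1e-12)
  }
})

test_that("Gx skips barely-expressed genes and errors on tiny inputs", {
  withr::local_seed(111)
  m <- matrix(rpois(20 * 5, 3), 20, 5)
  m[, 4] <- 0
  m[1:2, 4] <- 1 # expressed in only 2 cells
  em <- toy_cells(m, layer = "lognorm")
  sc <- as_stemness(rownames(em$values), runif(20))
  gx <- compute_gx(em, sc)
  expect_true(is.na(gx$spearman_r[4]))
  expect_false(gx$pass[4])

  expect_error(compute_gx(toy_cells(m[1:5, ], layer = "lognorm"),
                          as_stemness(rownames(m)[1:5], runif(5))),
               "at least 10")
})

test_that("Gy log fold change and Wilcoxon p behave on controlled inputs", {
  withr::local_seed(121)
  n <- 400
  mal <- rep(c(TRUE, FALSE), each = n / 2)
  m <- log1p(matrix(rpois(n * 4, 2), n, 4)) # log-normalized-scale values
  m[mal, 2] <- log1p(rpois(n / 2, 12))      # malignant-only high expression
  m[!mal, 2] <- 0
  em <- toy_cells(m, layer = "lognorm")
  gy <- compute_gy(em, mal)
  expect_lt(abs(gy$logfc[1]), 0.2)
  expect_false(gy$pass[1])
  expect_true(gy$pass[2])
  expect_gt(gy$logfc[2], 0.25)

  expect_error(compute_gy(em, rep(c(TRUE, FALSE), c(n - 2, 2))),
               "at least 3")
})

test_that("the vectorized Wilcoxon matches wilcox.test and the permutation oracle", {
  withr::local_seed(131)
  # base-R agreement (normal approximation, tie corrected, no continuity)
  n <- 40
  g1 <- rep(c(TRUE, FALSE), each = n / 2)
  m <- matrix(sample(0:5, n * 10, replace = TRUE), n, 10)
  em <- toy_cells(m, layer = "lognorm")
  gy <- compute_gy(em, g1, lfc_cutoff = -Inf)
  for (j in seq_len(10)) {
    ref <- suppressWarnings(
      wilcox.test(m[g1, j], m[!g1, j], exact = FALSE, correct = FALSE)
    )$p.value
    expect_equal(gy$p_value[j], ref, tolerance = 1e-10)
  }

  # exhaustive permutation oracle at 10 cells per group; the normal
  # approximation is tight on continuous data and a little looser under
  # heavy ties
  n2 <- 20
  g2 <- rep(c(TRUE, FALSE), each = 10)
  m_cont <- matrix(rexp(n2 * 4), n2, 4)
  gy_cont <- compute_gy(toy_cells(m_cont, layer = "lognorm"), g2,
                        lfc_cutoff = -Inf)
  for (j in seq_len(4)) {
    expect_lt(abs(gy_cont$p_value[j] - oracle_wilcox_perm(m_cont[, j], g2)),
              0.05)
  }
  m_tied <- matrix(sample(0:4, n2 * 4, replace = TRUE), n2, 4)
  gy_tied <- compute_gy(toy_cells(m_tied, layer = "lognorm"), g2,
                        lfc_cutoff = -Inf)
  for (j in seq_len(4)) {
    expect_lt(abs(gy_tied$p_value[j] - oracle_wilcox_perm(m_tied[, j], g2)),
              0.1)
  }
})

test_that("Gn is the set intersection of the two filters", {
  gx <- tibble::tibble(gene = c("A", "B", "C"), pass = c(TRUE, TRUE, FALSE))
  gy <- tibble::tibble(gene = c("B", "C", "D"), pass = c(TRUE, TRUE, TRUE))
  expect_equal(derive_gn(gx, gy), "B")
  gy2 <- tibble::tibble(gene = c("D", "E"), pass = c(TRUE, TRUE))
  expect_equal(derive_gn(gx, gy2), character(0))

  withr::local_seed(141)
  for (i in 1:5) {
    genes <- sprintf("G%02d", 1:40)
    gxr <- tibble::tibble(gene = genes, pass = runif(40) < 0.4)
    gyr <- tibble::tibble(gene = sample(genes), pass = runif(40) < 0.4)
    expect_equal(
      derive_gn(gxr, gyr),
      sort(intersect(gxr$gene[gxr$pass], gyr$gene[gyr$pass]))
    )
  }
})

test_that("signature aggregation uses qualifying-dataset geometric means", {
  contribs <- list(
    tibble::tibble(gene = c("A", "B"), spearman_r = c(0.4, 0.5)),
    tibble::tibble(gene = "A", spearman_r = 0.4),
    tibble::tibble(gene = "A", spearman_r = 0.4)
  )
  agg <- aggregate_signature(contribs, threshold = 0.4)
  # A: geometric mean exactly 0.4 -> excluded by the strict inequality
  expect_equal(agg$geometric_mean_r[agg$gene == "A"], 0.4)
  expect_false(agg$in_signature[agg$gene == "A"])
  # B: one dataset at 0.5 -> included at min_datasets = 1
  expect_true(agg$in_signature[agg$gene == "B"])
  # B drops out when two qualifying datasets are required
  agg2 <- aggregate_signature(contribs, min_datasets = 2)
  expect_false(agg2$in_signature[agg2$gene == "B"])
  expect_equal(agg2$n_datasets[agg2$gene == "A"], 3L)

  expect_error(
    aggregate_signature(list(tibble::tibble(gene = "A", spearman_r = -0.1))),
    "consistency"
  )
})

test_that("geometric means match the log-space oracle on random panels", {
  withr::local_seed(151)
  genes <- sprintf("G%02d", 1:30)
  contribs <- lapply(1:6, function(i) {
    g <- sample(genes, 12)
    tibble::tibble(gene = g, spearman_r = runif(12, 0.05, 0.95))
  })
  agg <- aggregate_signature(contribs, threshold = 0.4)
  pooled <- dplyr::bind_rows(contribs)
  for (g in agg$gene) {
    expect_equal(
      agg$geometric_mean_r[agg$gene == g],
      oracle_geomean(pooled$spearman_r[pooled$gene == g]),
      tolerance = 1e-12
    )
  }
})

test_that("raising the threshold never grows the signature", {
  withr::local_seed(161)
  contribs <- lapply(1:4, function(i) {
    tibble::tibble(gene = sample(sprintf("G%02d", 1:25), 10),
                   spearman_r = runif(10, 0.1, 0.9))
  })
  sizes <- vapply(c(0.2, 0.4, 0.6, 0.8), function(thr) {
    sum(aggregate_signature(contribs, threshold = thr)$in_signature)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("dropping a dataset never changes the other datasets' contributions", {
  withr::local_seed(171)
  contribs <- lapply(1:3, function(i) {
    tibble::tibble(gene = sprintf("G%02d", sample(1:20, 8)),
                   spearman_r = runif(8, 0.3, 0.8))
  })
  full <- aggregate_signature(contribs)
  drop1 <- aggregate_signature(contribs[-1])
  pooled <- dplyr::bind_rows(contribs[-1])
  for (g in drop1$gene) {
    expect_equal(
      drop1$geometric_mean_r[drop1$gene == g],
      oracle_geomean(pooled$spearman_r[pooled$gene == g]),
      tolerance = 1e-12
    )
  }
})
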