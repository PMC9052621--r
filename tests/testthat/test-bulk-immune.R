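test_that("samples with identical expression receive identical set scores", {
  withr::local_seed(201)
  m <- matrix(rnorm(20 * 4, 5), 20, 4,
              dimnames = list(sprintf("G%02d", 1:20), sprintf("s%d", 1:4)))
  m[, 2] <- m[, 1]
  em <- expr_mat(m, "lognorm", "gene_by_sample")
  sets <- list(A = sprintf("G%02d", 1:5), B = sprintf("G%02d", 10:16))
  sc <- gsva_like_score(em, sets)
  s1 <- dplyr::filter(sc, .data$sample_id == "s1")$score
  s2 <- dplyr::filter(sc, .data$sample_id == "s2")$score
  expect_equal(s1, s2)
})

test_that("a sample whose members occupy the top ranks attains the cohort maximum", {
  withr::local_seed(211)
  m <- matrix(rnorm(20 * 4, 0, 1), 20, 4,
              dimnames = list(sprintf("G%02d", 1:20), sprintf("s%d", 1:4)))
  members <- sprintf("G%02d", 1:4)
  m[members, 1] <- m[members, 1] + 50 # member genes dominate sample 1
  em <- expr_mat(m, "lognorm", "gene_by_sample")
  sc <- gsva_like_score(em, list(S = members))
  expect_equal(which.max(sc$score), 1L)
})

test_that("scores are invariant to gene-row permutation", {
  withr::local_seed(221)
  m <- matrix(rnorm(15 * 5, 3), 15, 5,
              dimnames = list(sprintf("G%02d", 1:15), sprintf("s%d", 1:5)))
  sets <- list(S = sprintf("G%02d", c(2, 5, 9)))
  em <- expr_mat(m, "lognorm", "gene_by_sample")
  perm <- sample(nrow(m))
  em2 <- expr_mat(m[perm, ], "lognorm", "gene_by_sample")
  expect_equal(gsva_like_score(em, sets), gsva_like_score(em2, sets))
})

test_that("both walk modes match the brute-force oracle on a 20-gene toy", {
  withr::local_seed(231)
  m <- matrix(rnorm(20 * 5, 5, 2), 20, 5,
              dimnames = list(sprintf("G%02d", 1:20), sprintf("s%d", 1:5)))
  em <- expr_mat(m, "lognorm", "gene_by_sample")
  members <- sprintf("G%02d", c(1, 4, 7, 12, 19))
  for (mode in c("max_dev", "pos_minus_neg")) {
    sc <- gsva_like_score(em, list(S = members), mode = mode)
    for (j in 1:5) {
      expect_equal(
        sc$score[j],
        oracle_gsva_sample(m, members, j, tau = 1, mode = mode),
        tolerance = 1e-12
      )
    }
  }
  # tau weighting also agrees
  sc2 <- gsva_like_score(em, list(S = members), tau = 0.5)
  expect_equal(sc2$score[2],
               oracle_gsva_sample(m, members, 2, tau = 0.5), tolerance = 1e-12)
})

test_that("an unmatched gene set is scored NA with a warning", {
  m <- matrix(rnorm(10 * 3, 2), 10, 3,
              dimnames = list(sprintf("G%02d", 1:10), sprintf("s%d", 1:3)))
  em <- expr_mat(m, "lognorm", "gene_by_sample")
  expect_warning(sc <- gsva_like_score(em, list(S = c("NOPE1", "NOPE2"))),
                 "no genes")
  expect_true(all(is.na(sc$score)))
})

test_that("marker abundance is the mean log2(x+1) over matched markers", {
  m <- matrix(c(1, 3, 7, 0,
                2, 2, 2, 2,
                0, 1, 3, 7), nrow = 3, byrow = TRUE,
              dimnames = list(c("M1", "M2", "M3"), sprintf("s%d", 1:4)))
  em <- expr_mat(m, "tpm_like", "gene_by_sample")
  one <- marker_abundance(em, list(S = "M1"))
  expect_equal(one$score, log2(m["M1", ] + 1), ignore_attr = TRUE)

  # hand-computed toy for a 2-marker set
  two <- marker_abundance(em, list(S = c("M1", "M3")))
  expect_equal(two$score,
               colMeans(log2(m[c("M1", "M3"), ] + 1)), ignore_attr = TRUE)

  # all markers at one shared value v: doubling (v+1) adds exactly 1 bit
  flat <- matrix(3, 2, 3, dimnames = list(c("A", "B"), sprintf("s%d", 1:3)))
  s1 <- marker_abundance(expr_mat(flat, "tpm_like", "gene_by_sample"),
                         list(S = c("A", "B")))$score
  s2 <- marker_abundance(
    expr_mat(2 * (flat + 1) - 1, "tpm_like", "gene_by_sample"),
    list(S = c("A", "B"))
  )$score
  expect_equal(s2 - s1, rep(1, 3))
})

test_that("score correlations match the rank-then-Pearson oracle", {
  withr::local_seed(241)
  x <- rnorm(40)
  expect_equal(correlate_scores(x, x)$estimate, 1)
  expect_equal(correlate_scores(x, -x)$estimate, -1)

  feats <- matrix(rnorm(40 * 4), 40, 4,
                  dimnames = list(NULL, paste0("f", 1:4)))
  res <- correlate_scores(x, feats)
  for (j in 1:4) {
    o <- oracle_spearman(feats[, j], x)
    expect_equal(res$estimate[j], o$r, tolerance = 1e-12)
    expect_equal(res$p_value[j], o$p, tolerance = 1e-12)
  }
  expect_equal(res$fdr, p.adjust(res$p_value, "BH"))
})

test_that("quadrant labels split on medians with at-median samples going low", {
  qs <- quadrant_stratify(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_equal(as.character(qs$labels$label),
               c("LSHT", "LSHT", "HSLT", "HSLT"))

  withr::local_seed(251)
  n <- 41
  qs2 <- quadrant_stratify(rnorm(n), rnorm(n))
  expect_equal(nrow(qs2$labels), n)
  expect_true(all(table(qs2$labels$label) >= 0))
  expect_equal(sum(table(qs2$labels$label)), n)
})

test_that("under the null, pairwise quadrant p-values are uniform", {
  withr::local_seed(261)
  reps <- 150
  pvals <- vapply(seq_len(reps), function(i) {
    stem <- rnorm(60)
    tmb <- rnorm(60)
    immune <- rnorm(60)
    qs <- quadrant_stratify(stem, tmb, immune)
    qs$comparisons$p_value[1] # fixed pair, raw p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("an anti-immune stemness axis reproduces the quadrant ordering", {
  withr::local_seed(271)
  n <- 2000
  stem <- rnorm(n)
  tmb <- rnorm(n)
  # immunity falls with stemness and rises with antigenicity (TMB)
  immune <- -stem + 0.5 * tmb + rnorm(n, sd = 0.5)
  qs <- quadrant_stratify(stem, tmb, immune)
  means <- tapply(immune, qs$labels$label, mean)
  expect_true(means["LSHT"] > means["LSLT"])
  expect_true(means["LSLT"] > means["HSHT"])
  expect_true(means["HSHT"] > means["HSLT"])
  expect_true(all(qs$comparisons$fdr < 0.05))
})

test_that("group-median correlation recovers a cross-group association", {
  withr::local_seed(281)
  groups <- rep(sprintf("type%02d", 1:12), each = 30)
  shift <- rep(rnorm(12, 0, 2), each = 30)
  stem <- shift + rnorm(360)
  feature <- 2 * shift + rnorm(360)
  res <- correlate_group_medians(stem, feature, groups)
  expect_equal(res$n_groups, 12L)
  expect_gt(res$estimate, 0.7)
  expect_error(correlate_group_medians(1:4, 1:4, c("a", "a", "b", "b")),
               "3 groups")
})
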