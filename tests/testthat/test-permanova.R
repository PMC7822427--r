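test_that("standardization and distances behave geometrically", {
  x <- rbind(c(0, 0), c(3, 4), c(0, 0))
  d <- standardize_and_distance(x, scale = FALSE)
  m <- as.matrix(d)
  expect_equal(m[1, 2], 5)
  expect_equal(m[1, 3], 0)
  # zero-variance column dropped with a warning
  x2 <- cbind(rnorm(6), rep(1, 6))
  colnames(x2) <- c("a", "b")
  expect_warning(standardize_and_distance(x2), "zero-variance")
  # triangle inequality on random matrices
  set.seed(8)
  for (rep in 1:20) {
    m <- as.matrix(standardize_and_distance(matrix(rnorm(5 * 3), 5)))
    for (i in 1:5) for (j in 1:5) for (k in 1:5) {
      expect_lte(m[i, j], m[i, k] + m[k, j] + 1e-12)
    }
  }
})

test_that("pseudo-F on 1-D Euclidean distances equals the ANOVA F", {
  a <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  p <- permanova(dist(c(1, 2, 3, 2, 3, 4, 3, 4, 5)),
                 rep(c("a", "b", "c"), each = 3), n_permutations = 99,
                 seed = 1)
  expect_equal(p$pseudo_F, a$F, tolerance = 1e-12)
  expect_equal(p$df_treatment, a$df_between)
  expect_equal(p$df_residual, a$df_within)
  set.seed(9)
  for (rep in 1:20) {
    x <- rnorm(15)
    g <- rep(c("a", "b", "c"), each = 5)
    expect_lt(abs(permanova(dist(x), g, 9, seed = rep)$pseudo_F -
                    one_way_anova(split(x, g))$F), 1e-10)
  }
})

test_that("the partition, R2 and p respect their constraints", {
  set.seed(10)
  x <- matrix(rnorm(16 * 5), 16)
  g <- rep(treatment_levels(), each = 4)
  res <- permanova(standardize_and_distance(x), g, n_permutations = 999,
                   seed = 2)
  expect_equal(res$SS_treatment + res$SS_residual, res$SS_total)
  expect_equal(res$R2, res$SS_treatment / res$SS_total)
  expect_equal(c(res$df_treatment, res$df_residual, res$df_total),
               c(3L, 12L, 15L))
  expect_gte(res$p, 1 / 1000)
  expect_true(res$R2 >= 0 && res$R2 <= 1)
  # two tight, far-separated clusters: smallest attainable p (clusters are
  # large enough that no permutation recreates the exact split)
  xc <- c(rnorm(10, 0, 0.01), rnorm(10, 100, 0.01))
  res2 <- permanova(dist(xc), rep(c("a", "b"), each = 10),
                    n_permutations = 999, seed = 3)
  expect_equal(res2$p, 1 / 1000)
  # permuting sample order with labels leaves the statistic unchanged
  perm <- sample(16)
  res3 <- permanova(standardize_and_distance(x[perm, ]), g[perm],
                    n_permutations = 99, seed = 4)
  expect_equal(res3$pseudo_F, res$pseudo_F, tolerance = 1e-12)
})

test_that("results agree with an independent reference implementation", {
  skip_if_not_installed("vegan")
  set.seed(12)
  x <- matrix(rnorm(16 * 6), 16)
  g <- rep(treatment_levels(), each = 4)
  d <- standardize_and_distance(x)
  mine <- permanova(d, g, n_permutations = 999, seed = 5)
  ref <- vegan::adonis2(d ~ g, permutations = 999)
  expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$R2, ref$R2[1], tolerance = 1e-10)
  expect_equal(mine$p, ref$`Pr(>F)`[1], tolerance = 0.05)
})

test_that("pairwise contrasts cover all pairs and adjust p-values", {
  set.seed(13)
  x <- matrix(rnorm(16 * 4), 16)
  g <- rep(treatment_levels(), each = 4)
  pw <- pairwise_permanova(standardize_and_distance(x), g,
                           n_permutations = 199, seed = 6)
  expect_equal(nrow(pw), choose(4, 2))
  expect_true(all(pw$p_adjusted >= pw$p))
  expect_equal(pw$p_adjusted, fdr_bh(pw$p))
})

test_that("Benjamini-Hochberg adjustment matches hand computations", {
  expect_equal(fdr_bh(0.03), 0.03)
  expect_equal(fdr_bh(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06)), rep(0.06, 6))
  expect_equal(fdr_bh(c(0.2, 0.2, 0.2)), rep(0.2, 3))
  sorted <- sort(runif(10))
  expect_true(!is.unsorted(fdr_bh(sorted)))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})
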