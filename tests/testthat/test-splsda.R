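test_that("one-hot encoding is a proper indicator matrix", {
  y <- one_hot(c("A", "B", "A"))
  expect_equal(unname(y), rbind(c(1, 0), c(0, 1), c(1, 0)))
  expect_equal(rowSums(y), c(1, 1, 1))
  expect_equal(unname(colSums(y)), c(2, 1))
  expect_error(one_hot(c("A", "A")), "2 classes")
})

test_that("soft thresholding keeps the right support", {
  expect_equal(soft_threshold_keep(c(0.5, -0.3, 0.1), 1), c(1, 0, 0))
  v <- c(0.4, -0.2, 0.7, 0.05)
  expect_equal(soft_threshold_keep(v, 4), v / sqrt(sum(v^2)))
  expect_equal(sum(soft_threshold_keep(v, 2) != 0), 2)
  # tied magnitudes at the boundary are all retained
  tied <- soft_threshold_keep(c(0.5, 0.5, 0.1), 1)
  expect_equal(sum(tied != 0), 2)
  expect_equal(sqrt(sum(tied^2)), 1)
  expect_error(soft_threshold_keep(v, 0), "\\[1, length")
  expect_error(soft_threshold_keep(v, 5), "\\[1, length")
})

test_that("sparse fit with full keepX matches the dense fit", {
  d <- planted_splsda_data(seed = 1, n_per_class = 10, p = 6,
                           noise = c(0.3, 0.3, 0.3))
  dense <- fit_plsda(d$X, d$labels, ncomp = 3)
  sparse <- fit_splsda(d$X, d$labels, ncomp = 3, keepX = ncol(d$X))
  expect_lt(max(abs(dense$scores - sparse$scores)), 1e-8)
  expect_lt(max(abs(dense$weights - sparse$weights)), 1e-8)
})

test_that("scores are orthogonal, weights unit-norm and keepX respected", {
  d <- planted_splsda_data(seed = 2, n_per_class = 8, p = 6,
                           noise = c(0.3, 0.3, 0.3))
  m <- fit_splsda(d$X, d$labels, ncomp = 3, keepX = c(1, 2, 3))
  expect_equal(unname(colSums(m$weights != 0)), c(1L, 2L, 3L))
  expect_equal(unname(sqrt(colSums(m$weights^2))), rep(1, 3))
  g <- crossprod(m$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  ev <- explained_variance_x(m)
  expect_true(all(ev >= 0 & ev <= 1))
  expect_lte(sum(ev), 1 + 1e-10)
  expect_error(fit_splsda(d$X, d$labels, ncomp = 3, keepX = 99), "keepX")
  expect_error(fit_splsda(d$X, d$labels, ncomp = 40), "ncomp")
  Xc <- d$X
  Xc[, 4] <- 1
  expect_error(fit_splsda(Xc, d$labels, ncomp = 2), "constant")
})

test_that("explained variance matches the deflation-residual oracle", {
  set.seed(14)
  X <- matrix(rnorm(30 * 6), 30)
  colnames(X) <- paste0("v", 1:6)
  g <- rep(treatment_levels(), length.out = 30)
  m <- fit_plsda(X, g, ncomp = 4)
  # oracle: successive squared-norm drops of the deflated matrix
  Xs <- scale(X)
  tot <- sum(Xs^2)
  drops <- numeric(4)
  for (h in 1:4) {
    t_h <- Xs %*% m$weights[, h]
    before <- sum(Xs^2)
    Xs <- Xs - t_h %*% t(crossprod(Xs, t_h) / sum(t_h^2))
    drops[h] <- (before - sum(Xs^2)) / tot
  }
  expect_equal(explained_variance_x(m), drops, tolerance = 1e-10)
  # rank-1 X: first component captures everything
  X1 <- outer(rnorm(20), rnorm(5)) + matrix(rnorm(100, sd = 1e-4), 20)
  colnames(X1) <- paste0("r", 1:5)
  m1 <- fit_plsda(X1, rep(c("a", "b"), 10), ncomp = 2)
  expect_gt(explained_variance_x(m1)[1], 0.99)
})

test_that("centroid prediction is exact on separable data and breaks ties first-class", {
  d <- planted_splsda_data(seed = 3)
  m <- fit_splsda(d$X, d$labels, ncomp = 3, keepX = 1)
  pr <- predict_centroid(m, d$X)
  expect_equal(as.character(pr$labels), as.character(d$labels))
  # scaling a raw feature and refitting leaves predictions unchanged
  X2 <- d$X
  X2[, 1] <- X2[, 1] * 50
  m2 <- fit_splsda(X2, d$labels, ncomp = 3, keepX = 1)
  pr2 <- predict_centroid(m2, X2)
  expect_equal(as.character(pr2$labels), as.character(pr$labels))
  # a point equidistant from two centroids goes to the first level
  Xt <- matrix(c(-1, -1, 1, 1, 0.5, -0.5), ncol = 1)
  mt <- fit_plsda(Xt, c("A", "A", "B", "B", "A", "B"), ncomp = 1)
  mid <- matrix(mean(Xt[1:4]), 1, 1)
  expect_equal(as.character(predict_centroid(mt, mid)$labels), "A")
  expect_error(predict_centroid(m, d$X[, 1:2]), "columns")
})

test_that("balanced error rate averages per-class error fractions", {
  expect_equal(balanced_error_rate(c("a", "a", "b"), c("a", "a", "b")), 0)
  expect_equal(balanced_error_rate(c("a", "b"), c("b", "a")), 1)
  expect_equal(balanced_error_rate(c("a", "a", "b", "b", "b", "b"),
                                   c("a", "x", "b", "b", "b", "b")), 0.25)
  # duplicating every member of every class leaves BER unchanged
  true <- c("a", "a", "b", "b", "b")
  pred <- c("a", "b", "b", "a", "b")
  expect_equal(balanced_error_rate(true, pred),
               balanced_error_rate(rep(true, 2), rep(pred, 2)))
  # duplicating only one class also leaves BER unchanged
  expect_equal(balanced_error_rate(c(true, "a", "a"), c(pred, "a", "b")),
               balanced_error_rate(true, pred))
  expect_error(balanced_error_rate(c("a"), c("a", "b")), "mismatch")
})

test_that("cross-validated performance is deterministic and detects signal", {
  d <- planted_splsda_data(seed = 4, n_per_class = 8)
  cv1 <- perf(d$X, d$labels, max_ncomp = 3, folds = 4, repeats = 5, seed = 9)
  cv2 <- perf(d$X, d$labels, max_ncomp = 3, folds = 4, repeats = 5, seed = 9)
  expect_identical(cv1, cv2)
  expect_true(all(cv1$ber >= 0 & cv1$ber <= 1))
  expect_lt(cv1$ber[3], 0.1)  # separable data: near-zero error by comp 3
})

test_that("tuning selects the planted sparsity and is seed-stable", {
  d <- planted_splsda_data(seed = 6)
  tn1 <- suppressWarnings(tune(d$X, d$labels, ncomp = 3, keepX_grid = 1:4,
                               folds = 4, repeats = 5, seed = 21))
  tn2 <- suppressWarnings(tune(d$X, d$labels, ncomp = 3, keepX_grid = 1:4,
                               folds = 4, repeats = 5, seed = 21))
  expect_identical(tn1$keepX, tn2$keepX)
  expect_equal(tn1$keepX, rep(1L, 3))
  # grid of only p reduces to the dense fit's performance
  tnp <- suppressWarnings(tune(d$X, d$labels, ncomp = 1,
                               keepX_grid = ncol(d$X), folds = 4,
                               repeats = 5, seed = 21))
  cvp <- suppressWarnings(perf(d$X, d$labels, max_ncomp = 1, folds = 4,
                               repeats = 5, seed = 21))
  expect_equal(tnp$curves[[1]]$ber, cvp$ber[1], tolerance = 1e-12)
  expect_error(tune(d$X, d$labels, keepX_grid = integer(0), seed = 1),
               "empty")
})

test_that("dense scores agree with an independent reference implementation", {
  skip_if_not_installed("mixOmics")
  d <- planted_splsda_data(seed = 7, n_per_class = 10, p = 6,
                           noise = c(0.3, 0.4, 0.5))
  mine <- fit_plsda(d$X, d$labels, ncomp = 3)
  ref <- mixOmics::plsda(d$X, d$labels, ncomp = 3)
  for (h in 1:3) {
    expect_gt(abs(cor(mine$scores[, h], ref$variates$X[, h])), 0.99)
  }
})

test_that("loading assignments follow the group-mean rule and flip with sign", {
  d <- planted_splsda_data(seed = 8)
  m <- fit_splsda(d$X, d$labels, ncomp = 1, keepX = 1)
  lg <- loading_group_assignment(m, d$X, d$labels, 1)
  expect_equal(nrow(lg), 1)
  j <- which(m$weights[, 1] != 0)
  gm <- tapply(scale(d$X)[, j], d$labels, mean)
  want <- names(gm)[if (lg$weight > 0) which.max(gm) else which.min(gm)]
  expect_equal(lg$group, want)
  # flipping the column flips the loading sign, not the assignment
  X2 <- d$X
  X2[, j] <- -X2[, j]
  m2 <- fit_splsda(X2, d$labels, ncomp = 1, keepX = 1)
  lg2 <- loading_group_assignment(m2, X2, d$labels, 1)
  expect_equal(lg2$group, lg$group)
  expect_equal(sign(lg2$weight), -sign(lg$weight))
  expect_error(loading_group_assignment(m, d$X, d$labels, 5), "range")
})

test_that("score correlations reproduce the closed-form Pearson values", {
  expect_equal(correlate_scores(cbind(1:4), c(2, 4, 6, 8))$r, 1)
  expect_equal(correlate_scores(cbind(1:4), c(8, 6, 4, 2))$r, -1)
  out <- correlate_scores(cbind(c(1, 2, 3)), c(2, 4, 5))
  expect_equal(round(out$r, 4), 0.982)
  expect_equal(out$p, cor.test(c(1, 2, 3), c(2, 4, 5))$p.value)
  expect_error(correlate_scores(cbind(1:4), rep(1, 4)), "zero variance")
})

test_that("models survive a JSON round-trip", {
  d <- planted_splsda_data(seed = 9)
  m <- fit_splsda(d$X, d$labels, ncomp = 2, keepX = c(1, 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_splsda_json(m, path)
  m2 <- read_splsda_json(path)
  expect_equal(m2$weights, m$weights)
  expect_equal(m2$center, m$center)
  expect_equal(m2$centroids, m$centroids)
  pr <- predict_centroid(m, d$X)
  pr2 <- predict_centroid(m2, d$X)
  expect_equal(as.character(pr$labels), as.character(pr2$labels))
  expect_equal(pr$scores, pr2$scores)
})
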