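#' One-hot class indicator matrix
#'
#' @param labels Factor or character vector with >= 2 classes.
#' @return n x k 0/1 matrix, columns named by class level, exactly one 1 per
#'   row.
#' @export
one_hot <- function(labels) {
  f <- if (is.factor(labels)) labels else factor(labels, levels = unique(labels))
  if (nlevels(f) < 2L) stop("need >= 2 classes", call. = FALSE)
  y <- matrix(0, length(f), nlevels(f),
              dimnames = list(names(labels), levels(f)))
  y[cbind(seq_along(f), as.integer(f))] <- 1
  y
}

#' Soft-threshold a weight vector to a fixed support size
#'
#' The sparsity operator of sparse PLS: subtracts the (keep+1)-th largest
#' absolute value from all magnitudes, clamps at zero, restores signs and
#' renormalizes to unit Euclidean norm. Exactly `keep` entries survive when
#' there are no ties at the threshold; tied entries are all retained.
#'
#' @param v Numeric vector.
#' @param keep Number of entries to retain, in `[1, length(v)]`.
#' @return Unit-norm vector with at most `length(v)` and typically `keep`
#'   nonzeros.
#' @examples
#' soft_threshold_keep(c(0.5, -0.3, 0.1), 1)  # c(1, 0, 0)
#' @export
soft_threshold_keep <- function(v, keep) {
  stopifnot(is.numeric(v), length(v) >= 1L)
  if (!is.numeric(keep) || length(keep) != 1L || keep < 1 ||
      keep > length(v)) {
    stop("`keep` must lie in [1, length(v)]", call. = FALSE)
  }
  a <- abs(v)
  if (keep >= length(v)) {
    thr <- 0
  } else {
    kth <- sort(a, decreasing = TRUE)[keep]
    below <- a[a < kth]
    # threshold at the largest magnitude strictly below the keep-th, so
    # entries tied with the keep-th all survive
    thr <- if (length(below)) max(below) else 0
  }
  out <- sign(v) * pmax(a - thr, 0)
  nrm <- sqrt(sum(out^2))
  if (nrm == 0) stop("cannot threshold an all-zero vector", call. = FALSE)
  out / nrm
}

.scale_x <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing values in X", call. = FALSE)
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  if (any(scl == 0)) {
    stop("constant column(s) in X: ",
         paste(colnames(x)[scl == 0], collapse = ", "), call. = FALSE)
  }
  list(x = sweep(sweep(x, 2L, ctr), 2L, scl, "/"), center = ctr, scale = scl)
}

# Core NIPALS-style fit shared by sparse and dense paths.
# keepX = NULL disables thresholding entirely (dense PLS-DA).
.pls_fit <- function(X, labels, ncomp, keepX = NULL, max_iter = 500,
                     tol = 1e-9) {
  f <- if (is.factor(labels)) droplevels(labels)
       else factor(labels, levels = unique(labels))
  sc <- .scale_x(X)
  Xc <- sc$x
  n <- nrow(Xc); p <- ncol(Xc)
  if (ncomp > min(n - 1L, p)) {
    stop("ncomp must be <= min(n - 1, p)", call. = FALSE)
  }
  if (!is.null(keepX)) {
    keepX <- rep_len(as.integer(keepX), ncomp)
    if (any(keepX < 1L) || any(keepX > p)) {
      stop("keepX values must lie in [1, ncol(X)]", call. = FALSE)
    }
  }
  Y <- one_hot(f)
  Yc <- sweep(Y, 2L, colMeans(Y))
  totvar <- sum(Xc^2)
  W <- matrix(0, p, ncomp, dimnames = list(colnames(Xc), NULL))
  P <- matrix(0, p, ncomp, dimnames = list(colnames(Xc), NULL))
  Q <- matrix(0, ncol(Y), ncomp, dimnames = list(colnames(Y), NULL))
  Tm <- matrix(0, n, ncomp, dimnames = list(rownames(X), NULL))
  ev <- numeric(ncomp)
  for (h in seq_len(ncomp)) {
    M <- crossprod(Xc, Yc)                     # p x k
    sv <- svd(M, nu = 1L, nv = 1L)
    w <- sv$u[, 1L]; v <- sv$v[, 1L]
    if (!is.null(keepX)) {
      for (it in seq_len(max_iter)) {
        w_new <- drop(M %*% v)
        w_new <- soft_threshold_keep(w_new, keepX[h])
        v_new <- drop(crossprod(M, w_new))
        v_new <- v_new / sqrt(sum(v_new^2))
        if (max(abs(w_new - w)) < tol) { w <- w_new; v <- v_new; break }
        w <- w_new; v <- v_new
      }
    }
    t_h <- drop(Xc %*% w)
    # deterministic sign anchored on the class structure: the class loading
    # with the largest magnitude is positive (scores then do not depend on
    # arbitrary sign flips of X columns or of the SVD)
    q_tmp <- drop(crossprod(Yc, t_h))
    if (q_tmp[which.max(abs(q_tmp))] < 0) {
      w <- -w
      t_h <- -t_h
    }
    tt <- sum(t_h^2)
    p_h <- drop(crossprod(Xc, t_h)) / tt
    q_h <- drop(crossprod(Yc, t_h)) / tt
    W[, h] <- w; P[, h] <- p_h; Q[, h] <- q_h; Tm[, h] <- t_h
    ev[h] <- tt * sum(p_h^2) / totvar
    Xc <- Xc - tcrossprod(t_h, p_h)
    Yc <- Yc - tcrossprod(t_h, q_h)
  }
  centroids <- do.call(rbind, lapply(levels(f), function(cl)
    colMeans(Tm[f == cl, , drop = FALSE])))
  rownames(centroids) <- levels(f)
  structure(list(
    weights = W, x_loadings = P, y_loadings = Q, scores = Tm,
    keepX = if (is.null(keepX)) rep(p, ncomp) else keepX,
    sparse = !is.null(keepX),
    center = sc$center, scale = sc$scale, levels = levels(f),
    labels = f, centroids = centroids, explained_variance = ev,
    ncomp = ncomp
  ), class = "splsda_model")
}

#' Fit a sparse PLS discriminant analysis model
#'
#' Partial least squares against the centered class-indicator matrix, with
#' per-component soft-thresholding of the X-weight vector so that at most
#' `keepX[h]` traits enter component h. Columns of X are centered and scaled
#' to unit variance (parameters stored in the model); the score of each
#' component is extracted, then X and the indicator matrix are deflated by
#' the rank-one regression on that score, which makes successive scores
#' orthogonal. Class centroids in score space support nearest-centroid
#' prediction.
#'
#' @param X Numeric samples x traits matrix (no missing values, no constant
#'   columns).
#' @param labels Class labels (>= 2 classes).
#' @param ncomp Number of latent components (`<= min(n - 1, p)`).
#' @param keepX Integer vector (recycled to `ncomp`) of traits retained per
#'   component; default `ncol(X)` (no sparsity).
#' @param max_iter,tol Convergence controls for the alternating sparse
#'   update.
#' @return Object of class `"splsda_model"`: `weights`, `x_loadings`,
#'   `y_loadings`, `scores`, `keepX`, scaling parameters, class `centroids`,
#'   per-component `explained_variance` (fraction of scaled-X variance).
#' @export
fit_splsda <- function(X, labels, ncomp = 2L, keepX = ncol(as.matrix(X)),
                       max_iter = 500, tol = 1e-9) {
  .pls_fit(X, labels, ncomp = ncomp, keepX = keepX, max_iter = max_iter,
           tol = tol)
}

#' Fit a dense PLS-DA model
#'
#' The unpenalized special case: per component the X-weight vector is the
#' leading left singular vector of the X'Y cross-covariance, with no
#' thresholding step. [fit_splsda()] with `keepX = ncol(X)` converges to the
#' same solution.
#'
#' @inheritParams fit_splsda
#' @return An `"splsda_model"` (with `sparse = FALSE`).
#' @export
fit_plsda <- function(X, labels, ncomp = 2L) {
  .pls_fit(X, labels, ncomp = ncomp, keepX = NULL)
}

#' Project new samples and classify by nearest centroid
#'
#' Applies the model's centering/scaling, computes scores by sequential
#' deflation with the model's loadings, and assigns each sample to the class
#' with the nearest centroid (Euclidean distance in score space). Ties break
#' deterministically to the first class in the model's level order.
#'
#' @param model A fitted `"splsda_model"`.
#' @param X_new Samples x traits matrix with the model's columns.
#' @param ncomp Number of components to use (default: all in the model).
#' @return List: `labels` (factor of predictions), `scores` (n x ncomp).
#' @export
predict_centroid <- function(model, X_new, ncomp = model$ncomp) {
  stopifnot(inherits(model, "splsda_model"), ncomp >= 1L,
            ncomp <= model$ncomp)
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$center)) {
    stop("X_new has wrong number of columns", call. = FALSE)
  }
  if (!is.null(colnames(X_new)) && !is.null(names(model$center)) &&
      !identical(colnames(X_new), names(model$center))) {
    stop("X_new columns do not match the model's", call. = FALSE)
  }
  Xc <- sweep(sweep(X_new, 2L, model$center), 2L, model$scale, "/")
  Tn <- matrix(0, nrow(Xc), ncomp)
  for (h in seq_len(ncomp)) {
    Tn[, h] <- drop(Xc %*% model$weights[, h])
    Xc <- Xc - tcrossprod(Tn[, h], model$x_loadings[, h])
  }
  cen <- model$centroids[, seq_len(ncomp), drop = FALSE]
  d2 <- outer(rowSums(Tn^2), rowSums(cen^2), "+") - 2 * tcrossprod(Tn, cen)
  pred <- model$levels[apply(d2, 1L, which.min)]  # which.min: first on ties
  list(labels = factor(pred, levels = model$levels), scores = Tn)
}

#' Balanced error rate
#'
#' Mean over the true classes of each class's misclassification fraction;
#' insensitive to class-size imbalance.
#'
#' @param true,predicted Equal-length label vectors; every true class must
#'   be non-empty.
#' @return Scalar in \[0, 1\].
#' @examples
#' balanced_error_rate(c("a", "a", "b"), c("a", "b", "b"))  # 0.25
#' @export
balanced_error_rate <- function(true, predicted) {
  true <- as.character(true); predicted <- as.character(predicted)
  if (length(true) != length(predicted)) {
    stop("length mismatch", call. = FALSE)
  }
  cls <- unique(true)
  mean(vapply(cls, function(cl) {
    ix <- true == cl
    mean(predicted[ix] != cl)
  }, numeric(1)))
}

# Stratified CV cannot use more folds than the smallest class has members;
# warn once and reduce.
.effective_folds <- function(labels, k) {
  min_cls <- min(table(as.character(labels)))
  if (k > min_cls) {
    warning("reducing folds from ", k, " to smallest class size ", min_cls,
            call. = FALSE)
    k <- min_cls
  }
  as.integer(k)
}

# Stratified fold assignment (k already validated against class sizes).
.make_folds <- function(labels, k) {
  f <- as.character(labels)
  k <- min(k, min(table(f)))
  fold <- integer(length(f))
  for (cl in unique(f)) {
    ix <- sample(which(f == cl))
    fold[ix] <- rep_len(sample.int(k), length(ix))
  }
  list(fold = fold, k = k)
}

#' Cross-validated performance curve for PLS-DA component selection
#'
#' Repeated stratified k-fold cross-validation of dense PLS-DA: for each
#' component count 1..`max_ncomp`, the overall and balanced error rates of
#' nearest-centroid classification, averaged over folds and repeats (SD over
#' repeats). With fewer members in the smallest class than `folds`, folds
#' are reduced with a warning.
#'
#' @param X Samples x traits matrix.
#' @param labels Class labels.
#' @param max_ncomp Largest component count assessed (default 5).
#' @param folds Cross-validation folds (default 5).
#' @param repeats Number of CV repeats (default 50).
#' @param seed Seed; repeat r uses stream `seed + r`.
#' @return Data.frame of class `"cv_curve"`: `ncomp`, `error_overall`,
#'   `error_overall_sd`, `ber`, `ber_sd`.
#' @export
perf <- function(X, labels, max_ncomp = 5L, folds = 5L, repeats = 50L, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  X <- as.matrix(X)
  f <- if (is.factor(labels)) droplevels(labels)
       else factor(labels, levels = unique(labels))
  if (folds > nrow(X)) stop("more folds than samples", call. = FALSE)
  folds <- .effective_folds(f, folds)
  max_ncomp <- min(max_ncomp, ncol(X))
  err <- array(NA_real_, c(repeats, max_ncomp, 2L))
  for (r in seq_len(repeats)) {
    set.seed(seed + r)
    fd <- .make_folds(f, folds)
    fold_err <- array(NA_real_, c(fd$k, max_ncomp, 2L))
    for (k in seq_len(fd$k)) {
      test <- fd$fold == k
      m <- fit_plsda(X[!test, , drop = FALSE], f[!test],
                     ncomp = min(max_ncomp, sum(!test) - 1L))
      for (h in seq_len(m$ncomp)) {
        pr <- predict_centroid(m, X[test, , drop = FALSE], ncomp = h)$labels
        fold_err[k, h, 1L] <- mean(pr != f[test])
        fold_err[k, h, 2L] <- balanced_error_rate(f[test], pr)
      }
    }
    err[r, , ] <- apply(fold_err, c(2L, 3L), mean, na.rm = TRUE)
  }
  out <- data.frame(
    ncomp = seq_len(max_ncomp),
    error_overall = apply(err[, , 1L, drop = FALSE], 2L, mean),
    error_overall_sd = apply(err[, , 1L, drop = FALSE], 2L, stats::sd),
    ber = apply(err[, , 2L, drop = FALSE], 2L, mean),
    ber_sd = apply(err[, , 2L, drop = FALSE], 2L, stats::sd)
  )
  class(out) <- c("cv_curve", class(out))
  out
}

#' Tune the number of traits kept per sPLS-DA component
#'
#' Greedy per-component selection: holding the keepX values already chosen
#' for earlier components fixed, each candidate grid value for the current
#' component is scored by repeated stratified cross-validated balanced error
#' rate (nearest-centroid prediction using all components up to the current
#' one); the smallest candidate attaining the minimal mean BER wins
#' (parsimony tie-break).
#'
#' @inheritParams perf
#' @param ncomp Number of components to tune.
#' @param keepX_grid Candidate numbers of traits per component.
#' @return List of class `"splsda_tune"`: `keepX` (chosen vector), `curves`
#'   (per component, data.frame `keepX`, `ber`, `ber_sd`).
#' @export
tune <- function(X, labels, ncomp = 2L, keepX_grid = NULL, folds = 5L,
                 repeats = 50L, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  X <- as.matrix(X)
  f <- if (is.factor(labels)) droplevels(labels)
       else factor(labels, levels = unique(labels))
  if (is.null(keepX_grid)) {
    keepX_grid <- unique(pmin(c(1:5, 10, ncol(X)), ncol(X)))
  }
  keepX_grid <- sort(unique(as.integer(keepX_grid)))
  if (!length(keepX_grid)) stop("empty keepX grid", call. = FALSE)
  if (any(keepX_grid < 1L) || any(keepX_grid > ncol(X))) {
    stop("keepX grid values must lie in [1, ncol(X)]", call. = FALSE)
  }
  folds <- .effective_folds(f, folds)
  chosen <- integer(0)
  curves <- vector("list", ncomp)
  for (h in seq_len(ncomp)) {
    ber_mat <- matrix(NA_real_, repeats, length(keepX_grid))
    for (r in seq_len(repeats)) {
      set.seed(seed + r)
      fd <- .make_folds(f, folds)
      fold_ber <- matrix(NA_real_, fd$k, length(keepX_grid))
      for (k in seq_len(fd$k)) {
        test <- fd$fold == k
        for (gi in seq_along(keepX_grid)) {
          m <- fit_splsda(X[!test, , drop = FALSE], f[!test], ncomp = h,
                          keepX = c(chosen, keepX_grid[gi]))
          pr <- predict_centroid(m, X[test, , drop = FALSE],
                                 ncomp = h)$labels
          fold_ber[k, gi] <- balanced_error_rate(f[test], pr)
        }
      }
      ber_mat[r, ] <- colMeans(fold_ber, na.rm = TRUE)
    }
    mean_ber <- colMeans(ber_mat)
    best <- keepX_grid[which.min(mean_ber)]  # smallest at the minimum
    chosen <- c(chosen, best)
    curves[[h]] <- data.frame(keepX = keepX_grid, ber = mean_ber,
                              ber_sd = apply(ber_mat, 2L, stats::sd))
  }
  structure(list(keepX = chosen, curves = curves), class = "splsda_tune")
}

#' Explained X-variance per component
#'
#' Fraction of the total centered-and-scaled X variance captured by each
#' component's rank-one reconstruction from its score; equals the drop in
#' squared Frobenius norm at each deflation step, so the cumulative sum is
#' bounded by 1.
#'
#' @param model A fitted `"splsda_model"`.
#' @return Numeric vector of per-component fractions.
#' @export
explained_variance_x <- function(model) {
  stopifnot(inherits(model, "splsda_model"))
  model$explained_variance
}

#' Assign each selected trait of a component to a treatment
#'
#' For every trait with a nonzero weight on the given component, finds the
#' class whose group mean of that (scaled) trait is maximal when the loading
#' weight is positive, or minimal when it is negative -- the coloring rule
#' of loading-contribution plots.
#'
#' @param model A fitted `"splsda_model"`.
#' @param X,labels The training data the model was fitted on.
#' @param component Component index.
#' @return Data.frame per selected trait: `trait`, `weight`, `group`
#'   (assigned class), `tie` flag.
#' @export
loading_group_assignment <- function(model, X, labels, component = 1L) {
  stopifnot(inherits(model, "splsda_model"))
  if (component < 1L || component > model$ncomp) {
    stop("component out of range", call. = FALSE)
  }
  X <- as.matrix(X)
  f <- if (is.factor(labels)) droplevels(labels)
       else factor(labels, levels = unique(labels))
  Xs <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  w <- model$weights[, component]
  sel <- which(w != 0)
  rows <- lapply(sel, function(j) {
    gm <- vapply(levels(f), function(cl) mean(Xs[f == cl, j]), numeric(1))
    target <- if (w[j] > 0) max(gm) else min(gm)
    hits <- names(gm)[abs(gm - target) < 1e-12]
    data.frame(trait = colnames(X)[j], weight = unname(w[j]),
               group = hits[1L], tie = length(hits) > 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation of latent scores with plant weights
#'
#' Product--moment correlation (with two-sided t-test p-value) between each
#' score column and an external covariate such as plant fresh or dry weight.
#'
#' @param scores Numeric matrix (samples x components) or vector.
#' @param covariate Numeric vector, same number of samples (>= 3).
#' @return Data.frame per component: `component`, `r`, `p`.
#' @export
correlate_scores <- function(scores, covariate) {
  scores <- as.matrix(scores)
  if (nrow(scores) != length(covariate) || nrow(scores) < 3L) {
    stop("scores and covariate need equal length >= 3", call. = FALSE)
  }
  if (stats::sd(covariate) == 0) {
    stop("covariate has zero variance", call. = FALSE)
  }
  rows <- lapply(seq_len(ncol(scores)), function(h) {
    if (stats::sd(scores[, h]) == 0) {
      stop("score column ", h, " has zero variance", call. = FALSE)
    }
    ct <- stats::cor.test(scores[, h], covariate)
    data.frame(component = h, r = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, rows)
}

#' Serialize / restore an sPLS-DA model as JSON
#'
#' @param model A fitted `"splsda_model"`.
#' @param path File path for the JSON document.
#' @return `write_splsda_json` returns `path` invisibly; `read_splsda_json`
#'   returns the restored `"splsda_model"` (scores and labels included).
#' @export
write_splsda_json <- function(model, path) {
  stopifnot(inherits(model, "splsda_model"))
  obj <- list(
    weights = model$weights, x_loadings = model$x_loadings,
    y_loadings = model$y_loadings, scores = model$scores,
    keepX = model$keepX, sparse = model$sparse,
    center = as.list(model$center), scale = as.list(model$scale),
    levels = model$levels, labels = as.character(model$labels),
    centroids = model$centroids,
    explained_variance = model$explained_variance, ncomp = model$ncomp
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_splsda_json
#' @export
read_splsda_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- obj
  m$center <- unlist(obj$center)
  m$scale <- unlist(obj$scale)
  m$weights <- matrix(obj$weights, ncol = obj$ncomp,
                      dimnames = list(names(m$center), NULL))
  m$x_loadings <- matrix(obj$x_loadings, ncol = obj$ncomp,
                         dimnames = list(names(m$center), NULL))
  m$y_loadings <- matrix(obj$y_loadings, ncol = obj$ncomp,
                         dimnames = list(obj$levels, NULL))
  m$scores <- matrix(obj$scores, ncol = obj$ncomp)
  m$centroids <- matrix(obj$centroids, ncol = obj$ncomp,
                        dimnames = list(obj$levels, NULL))
  m$labels <- factor(obj$labels, levels = obj$levels)
  class(m) <- "splsda_model"
  m
}
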