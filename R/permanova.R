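#' Standardize a trait matrix and compute a distance matrix
#'
#' Centers each trait column and scales it to unit variance (traits carry
#' heterogeneous units, so z-scoring puts them on a common footing), then
#' computes pairwise distances. Zero-variance columns are dropped with a
#' warning.
#'
#' @param x Numeric matrix or data.frame of samples x traits (row names =
#'   sample ids). Non-numeric columns of a data.frame are dropped.
#' @param method Distance metric passed to [stats::dist()] (default
#'   `"euclidean"`).
#' @param scale Standardize columns first (default TRUE).
#' @return Object of class `"dist"` with attributes `metric` and `ids`.
#' @export
standardize_and_distance <- function(x, method = "euclidean", scale = TRUE) {
  if (is.data.frame(x)) {
    x <- as.matrix(x[vapply(x, is.numeric, logical(1))])
  }
  stopifnot(is.matrix(x), is.numeric(x))
  if (nrow(x) < 2L) stop("need >= 2 samples", call. = FALSE)
  if (anyNA(x)) stop("missing cells in trait matrix", call. = FALSE)
  if (scale) {
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0)) {
      warning("dropping zero-variance column(s): ",
              paste(colnames(x)[sds == 0], collapse = ", "))
      x <- x[, sds > 0, drop = FALSE]
      sds <- sds[sds > 0]
    }
    if (!ncol(x)) stop("no non-constant columns left", call. = FALSE)
    x <- base::scale(x, center = TRUE, scale = sds)
  }
  d <- stats::dist(x, method = method)
  attr(d, "metric") <- method
  attr(d, "ids") <- rownames(x)
  d
}

# Sum-of-squares partition of a squared-distance matrix for given labels.
# total SS = sum_{i<j} d_ij^2 / N; within SS = per-group pair sums / n_g.
.permanova_ss <- function(d2, idx_by_group) {
  n <- nrow(d2)
  ss_total <- sum(d2) / (2 * n)
  ss_within <- sum(vapply(idx_by_group, function(ix)
    sum(d2[ix, ix]) / (2 * length(ix)), numeric(1)))
  c(total = ss_total, within = ss_within, between = ss_total - ss_within)
}

.pseudo_f <- function(d2, idx_by_group, df_a, df_w) {
  ss <- .permanova_ss(d2, idx_by_group)
  (ss[["between"]] / df_a) / (ss[["within"]] / df_w)
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the sum of squared inter-point distances between and within
#' groups and tests the pseudo-F statistic
#' `(SS_between/df_between) / (SS_within/df_within)` by free permutation of
#' the group labels. The observed statistic is included in the permutation
#' reference set, so `p >= 1/(n_permutations + 1)`. On one-dimensional
#' Euclidean data the pseudo-F equals the classical one-way ANOVA F.
#'
#' @param d A `"dist"` object or symmetric distance matrix.
#' @param groups Group labels, one per sample (>= 2 groups, each >= 2
#'   samples).
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Seed for the permutations (required).
#' @return List of class `"permanova"`: degrees of freedom, sums of squares,
#'   `R2`, `pseudo_F`, `p`, `n_permutations`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed) {
  d2 <- .as_d2(d)
  n <- nrow(d2)
  groups <- as.character(groups)
  if (length(groups) != n) stop("length(groups) != n samples", call. = FALSE)
  tab <- table(groups)
  if (length(tab) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(tab < 2L)) stop("every group needs >= 2 samples", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(n_permutations >= 1)
  k <- length(tab)
  df_a <- k - 1L
  df_w <- n - k
  idx <- split(seq_len(n), groups)
  ss <- .permanova_ss(d2, idx)
  f_obs <- (ss[["between"]] / df_a) / (ss[["within"]] / df_w)
  set.seed(seed)
  sizes <- lengths(idx)
  f_perm <- vapply(seq_len(n_permutations), function(b) {
    perm <- sample.int(n)
    ix <- split(perm, rep.int(seq_along(sizes), sizes))
    .pseudo_f(d2, ix, df_a, df_w)
  }, numeric(1))
  p <- (sum(f_perm >= f_obs) + 1) / (n_permutations + 1)
  structure(list(
    df_treatment = df_a, df_residual = df_w, df_total = n - 1L,
    SS_treatment = unname(ss[["between"]]),
    SS_residual = unname(ss[["within"]]),
    SS_total = unname(ss[["total"]]),
    R2 = unname(ss[["between"]] / ss[["total"]]),
    pseudo_F = unname(f_obs), p = p,
    n_permutations = as.integer(n_permutations)
  ), class = "permanova")
}

.as_d2 <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-8) ||
      any(diag(m) != 0) || any(m < 0)) {
    stop("`d` must be a symmetric non-negative distance matrix with zero diagonal",
         call. = FALSE)
  }
  m^2
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (", x$n_permutations, " permutations)\n", sep = "")
  tab <- data.frame(
    df = c(x$df_treatment, x$df_residual, x$df_total),
    SS = c(x$SS_treatment, x$SS_residual, x$SS_total),
    R2 = c(x$R2, 1 - x$R2, 1),
    F = c(x$pseudo_F, NA, NA),
    p = c(x$p, NA, NA),
    row.names = c("Treatment", "Residual", "Total"))
  print(tab, digits = 5, na.print = "")
  invisible(x)
}

#' Pairwise PERMANOVA contrasts with FDR correction
#'
#' Runs a two-group PERMANOVA on every pair of groups (restricted to that
#' pair's samples) and adjusts the permutation p-values across pairs by the
#' Benjamini--Hochberg false discovery rate procedure.
#'
#' @inheritParams permanova
#' @return Data.frame per pair: `group1`, `group2`, `pseudo_F`, `R2`, `p`,
#'   `p_adjusted`.
#' @export
pairwise_permanova <- function(d, groups, n_permutations = 999, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  d2m <- sqrt(.as_d2(d))  # validated distance matrix
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) < 2L) stop("need >= 2 groups", call. = FALSE)
  pairs <- utils::combn(lev, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    keep <- groups %in% c(a, b)
    res <- permanova(stats::as.dist(d2m[keep, keep, drop = FALSE]),
                     groups[keep], n_permutations = n_permutations,
                     seed = seed + j)
    data.frame(group1 = a, group2 = b, pseudo_F = res$pseudo_F, R2 = res$R2,
               p = res$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- fdr_bh(out$p)
  out
}

#' Benjamini--Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values: monotone, capped at 1, identical inputs map to
#' identical outputs.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' fdr_bh(c(0.005, 0.5))  # 0.01, 0.50
#' @export
fdr_bh <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
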