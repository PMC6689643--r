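#' Principal component analysis of shape
#'
#' Eigendecomposition of the coordinate covariance of the (symmetric)
#' shape components about their mean, giving orthogonal axes of shape
#' variation. A deterministic sign convention (the largest-magnitude
#' element of each loading made positive) keeps axis directions
#' reproducible across runs and platforms.
#'
#' @param shapes an `aligned_shapes` object, or a k x d x n array, or an
#'   n x (k*d) matrix of vectorized shapes.
#' @param component which component of an `aligned_shapes` to analyse.
#' @return A `shape_pca`: `scores` (n x m), `loadings` ((k*d) x m,
#'   orthonormal), `eigenvalues`, `variance_fraction`, `consensus` (k x d
#'   mean of the analysed shapes), `k`, `d`, `ids`.
#' @export
shape_pca <- function(shapes, component = c("symmetric", "aligned")) {
  component <- match.arg(component)
  info <- shape_matrix(shapes, component)
  x <- info$x
  n <- nrow(x)
  if (n < 3) stop("PCA needs at least 3 specimens")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  cv <- crossprod(xc) / (n - 1)
  eg <- eigen(cv, symmetric = TRUE)
  rank <- min(n - 1, ncol(x))
  vals <- pmax(eg$values[seq_len(rank)], 0)
  load <- eg$vectors[, seq_len(rank), drop = FALSE]
  for (j in seq_len(rank)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  scores <- xc %*% load
  colnames(scores) <- colnames(load) <- paste0("PC", seq_len(rank))
  rownames(scores) <- info$ids
  structure(list(scores = scores, loadings = load, eigenvalues = vals,
                 variance_fraction = vals / sum(vals),
                 consensus = matrix(mu, info$k, info$d),
                 k = info$k, d = info$d, ids = info$ids),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  m <- min(10, length(x$eigenvalues))
  cat(sprintf("shape PCA: %d axes; first %d explain %.1f%% of variance\n",
              length(x$eigenvalues), m,
              100 * sum(x$variance_fraction[seq_len(m)])))
  invisible(x)
}

shape_matrix <- function(shapes, component = "symmetric") {
  if (inherits(shapes, "aligned_shapes")) {
    arr <- shapes[[component]]
    list(x = t(apply(arr, 3, as.vector)), k = dim(arr)[1], d = dim(arr)[2],
         ids = shapes$ids)
  } else if (length(dim(shapes)) == 3L) {
    ids <- dimnames(shapes)[[3]]
    if (is.null(ids)) ids <- sprintf("spec_%d", seq_len(dim(shapes)[3]))
    list(x = t(apply(shapes, 3, as.vector)), k = dim(shapes)[1],
         d = dim(shapes)[2], ids = ids)
  } else {
    ids <- rownames(shapes)
    if (is.null(ids)) ids <- sprintf("spec_%d", seq_len(nrow(shapes)))
    list(x = as.matrix(shapes), k = ncol(shapes), d = 1L, ids = ids)
  }
}

#' Retain leading principal components, with a distance diagnostic
#'
#' Returns the first `m` PC scores together with the diagnostic used to
#' justify the reduction: the Pearson correlation between pairwise
#' Euclidean distances in the m-dimensional score space and the full
#' Procrustes (tangent-space) distances, plus the cumulative variance
#' fraction. A correlation near 1 indicates the retained axes summarize the
#' shape variation well.
#'
#' @param pca a `shape_pca`.
#' @param m number of leading components to keep.
#' @return List with `scores` (n x m), `distance_correlation`,
#'   `cumulative_variance`.
#' @export
retain_pcs <- function(pca, m) {
  rank <- ncol(pca$scores)
  if (m < 1 || m > rank) stop("m must be between 1 and the PCA rank")
  scores <- pca$scores[, seq_len(m), drop = FALSE]
  d_m <- stats::dist(scores)
  d_full <- stats::dist(pca$scores)
  r <- if (stats::sd(d_m) == 0 || stats::sd(d_full) == 0) NA_real_
       else stats::cor(as.vector(d_m), as.vector(d_full))
  list(scores = scores, distance_correlation = r,
       cumulative_variance = sum(pca$variance_fraction[seq_len(m)]))
}

#' Size adjustment of shape by pooled multivariate regression
#'
#' Regresses every shape coordinate on log centroid size, pools the
#' explained and total sums of squares over coordinates into a single
#' R-squared, and assesses it with a permutation test on the size labels
#' (the observed statistic counted among the permutations). The residuals
#' — size-adjusted shapes — can be fed back into [shape_pca()] for
#' allometry-free analyses.
#'
#' @param shapes an `aligned_shapes` (symmetric component used) or an
#'   n x p shape matrix.
#' @param size numeric vector of log centroid sizes (defaults to the ones
#'   stored in `shapes`).
#' @param permutations number of label permutations.
#' @param seed RNG seed for the permutations.
#' @return List with `residuals` (n x p matrix), `r_squared`, `p_value`,
#'   `permutations`.
#' @export
size_adjust <- function(shapes, size = NULL, permutations = 9999,
                        seed = 1L) {
  if (inherits(shapes, "aligned_shapes")) {
    if (is.null(size)) size <- shapes$log_centroid_size
    x <- shape_matrix(shapes, "symmetric")$x
  } else x <- as.matrix(shapes)
  n <- nrow(x)
  if (n <= 2) stop("size adjustment needs n > 2")
  if (length(size) != n) stop("size length must match specimen count")
  if (stats::sd(size) == 0) stop("constant size vector")
  if (permutations < 99) stop("use at least 99 permutations")

  yc <- sweep(x, 2, colMeans(x))
  ss_tot <- sum(yc^2)
  r2_of <- function(s) {
    sc <- s - mean(s)
    # pooled R^2 of coordinate-wise simple regressions on a shared predictor
    sum(drop(crossprod(yc, sc))^2) / sum(sc^2) / ss_tot
  }
  sc <- size - mean(size)
  beta <- drop(crossprod(yc, sc)) / sum(sc^2)
  fitted <- outer(sc, beta)
  resid <- yc - fitted
  r2 <- sum(fitted^2) / ss_tot

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  perm_r2 <- vapply(seq_len(permutations),
                    function(i) r2_of(sample(size)), numeric(1))
  p <- (1 + sum(perm_r2 >= r2)) / (permutations + 1)
  rownames(resid) <- rownames(x)
  list(residuals = resid, r_squared = r2, p_value = p,
       permutations = permutations)
}

get_rng_state <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
}

restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, globalenv())
}

#' Extreme shapes along a principal component
#'
#' Folds a PC loading back into landmark coordinates at
#' `consensus +/- magnitude * sqrt(eigenvalue) * loading`, the standard way
#' to visualize the shape change an axis describes (e.g. -3 to +3 s.d.
#' wireframes).
#'
#' @param pca a `shape_pca`.
#' @param axis PC index.
#' @param magnitude displacement in standard-deviation units of the axis.
#' @return List with `minus` and `plus`, each a k x d matrix.
#' @export
axis_extremes <- function(pca, axis = 1, magnitude = 3) {
  if (axis < 1 || axis > ncol(pca$loadings)) stop("axis out of range")
  disp <- magnitude * sqrt(pca$eigenvalues[axis]) *
    matrix(pca$loadings[, axis], pca$k, pca$d)
  list(minus = pca$consensus - disp, plus = pca$consensus + disp)
}
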