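#' Centroid size
#'
#' Square root of the summed squared distances of the landmarks from their
#' centroid — the standard geometric-morphometric size measure. Its natural
#' log is the "size" variable used in the allometry models.
#'
#' @param coords a k x d matrix or a k x d x n array.
#' @return A positive number, or a vector of n of them for an array.
#' @export
centroid_size <- function(coords) {
  if (length(dim(coords)) == 3L)
    return(apply(coords, 3, centroid_size))
  cen <- sweep(coords, 2, colMeans(coords))
  cs <- sqrt(sum(cen^2))
  if (cs <= .Machine$double.eps)
    stop("degenerate configuration: all landmarks coincide (zero centroid size)")
  cs
}

center_config <- function(coords) sweep(coords, 2, colMeans(coords))

unit_config <- function(coords) {
  cen <- center_config(coords)
  cen / sqrt(sum(cen^2))
}

#' Ordinary Procrustes alignment of two configurations
#'
#' Finds the proper rotation (reflections excluded by a determinant
#' correction on the SVD) that best superimposes `moving` onto `target` in
#' the least-squares sense. Both configurations are centred and scaled to
#' unit centroid size before rotation, so the returned residual is the
#' partial Procrustes distance between the two shapes.
#'
#' @param moving,target k x d coordinate matrices over the same landmarks.
#' @return List with `aligned` (rotated unit-size `moving`), `rotation`
#'   (d x d, det +1), `target` (unit-size), and `residual` (root summed
#'   squared difference).
#' @export
opa_align <- function(moving, target) {
  if (!all(dim(moving) == dim(target)))
    stop("configurations must share dimensions")
  a <- unit_config(moving)
  b <- unit_config(target)
  if (qr(a)$rank < 2 || qr(b)$rank < 2)
    stop("degenerate configuration (rank < 2): collinear landmarks")
  r <- procrustes_rotation(a, b)
  aligned <- a %*% r
  list(aligned = aligned, rotation = r, target = b,
       residual = sqrt(sum((aligned - b)^2)))
}

# proper rotation R minimising ||a R - b||, via SVD of a'b with the
# smallest singular value's sign flipped when det would be negative
procrustes_rotation <- function(a, b) {
  s <- svd(crossprod(a, b))
  d <- ncol(a)
  sgn <- diag(1, d)
  if (det(s$u %*% t(s$v)) < 0) sgn[d, d] <- -1
  s$u %*% sgn %*% t(s$v)
}

#' Generalized Procrustes analysis with object-symmetry decomposition
#'
#' Superimposes a set of landmark configurations by iterative alignment to a
#' consensus: all configurations are centred, fixed at unit centroid size
#' (partial Procrustes), and rotated (proper rotations only) until the
#' root-mean-square change of the consensus falls below `tol`. With
#' `reflect_relabel = TRUE` (object symmetry), each specimen contributes
#' both its original and its reflected-and-relabelled copy; the symmetric
#' component of a specimen is the average of its two aligned copies and the
#' asymmetric component half their difference, so
#' `symmetric + asymmetric` reconstructs the aligned original exactly.
#'
#' The converged consensus is rotated into a canonical frame: for symmetric
#' analyses the symmetry-plane normal becomes axis 1 and the in-plane
#' principal axes become axes 2 and 3 (principal axes throughout otherwise),
#' with a deterministic sign rule, so results are reproducible and do not
#' depend on the input orientation. Aligned coordinates are then (optionally)
#' projected orthogonally onto the tangent space at the consensus, the usual
#' linearization under which Euclidean statistics on shape apply.
#'
#' @param landmarks a `landmark_set`, or a k x d x n array plus `scheme`.
#' @param reflect_relabel include reflected copies (object symmetry).
#' @param tangent project aligned shapes to the tangent space at the
#'   consensus.
#' @param tol convergence tolerance on the consensus RMS change.
#' @param max_iter maximum GPA iterations.
#' @param scheme required when `landmarks` is a bare array.
#' @return An `aligned_shapes` object: `aligned`, `symmetric`, `asymmetric`
#'   (k x d x n arrays), `mean_shape` (k x d), `centroid_size`,
#'   `log_centroid_size`, `ids`, `scheme`, `iterations`, `residual_trace`.
#' @export
gpa <- function(landmarks, reflect_relabel = TRUE, tangent = TRUE,
                tol = 1e-10, max_iter = 100, scheme = NULL) {
  if (inherits(landmarks, "landmark_set")) {
    coords <- landmarks$coords; ids <- landmarks$ids
    scheme <- landmarks$scheme
  } else {
    coords <- landmarks
    ids <- dimnames(coords)[[3]]
    if (is.null(ids)) ids <- sprintf("spec_%d", seq_len(dim(coords)[3]))
    if (is.null(scheme)) stop("scheme required for bare arrays")
  }
  n <- dim(coords)[3]
  if (n < 2) stop("GPA needs at least two configurations")
  k <- scheme$k; d <- scheme$dimension

  cs <- apply(coords, 3, centroid_size)
  work <- coords
  for (i in seq_len(n)) work[, , i] <- unit_config(coords[, , i])
  if (reflect_relabel) {
    refl <- work
    for (i in seq_len(n)) refl[, , i] <- reflect_relabel(work[, , i], scheme)
    work <- array(c(work, refl), c(k, d, 2L * n))
  }
  m <- dim(work)[3]

  consensus <- work[, , 1]
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    for (i in seq_len(m))
      work[, , i] <- work[, , i] %*% procrustes_rotation(work[, , i], consensus)
    new_con <- unit_config(apply(work, c(1, 2), mean))
    delta <- sqrt(mean((new_con - consensus)^2))
    trace <- c(trace, delta)
    consensus <- new_con
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf(
      "GPA did not converge in %d iterations; residual trace tail: %s",
      max_iter, paste(signif(utils::tail(trace, 3), 3), collapse = ", ")))

  rot <- canonical_orientation(consensus, scheme,
                               symmetric = reflect_relabel)
  consensus <- consensus %*% rot
  for (i in seq_len(m)) {
    w <- work[, , i] %*% rot
    work[, , i] <- w %*% procrustes_rotation(w, consensus)
  }

  aligned <- work[, , seq_len(n), drop = FALSE]
  if (reflect_relabel) {
    refl <- work[, , n + seq_len(n), drop = FALSE]
    symmetric <- (aligned + refl) / 2
    asymmetric <- (aligned - refl) / 2
  } else {
    symmetric <- aligned
    asymmetric <- array(0, dim(aligned))
  }
  if (tangent) {
    aligned <- tangent_project(aligned, consensus)
    symmetric <- tangent_project(symmetric, consensus)
  }
  dn <- list(scheme$names, axis_letters(d), ids)
  dimnames(aligned) <- dimnames(symmetric) <- dimnames(asymmetric) <- dn
  structure(list(aligned = aligned, symmetric = symmetric,
                 asymmetric = asymmetric, mean_shape = consensus,
                 centroid_size = stats::setNames(cs, ids),
                 log_centroid_size = stats::setNames(log(cs), ids),
                 ids = ids, scheme = scheme, tangent = tangent,
                 iterations = it, residual_trace = trace),
            class = "aligned_shapes")
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat(sprintf(
    "aligned shapes: %d specimens, %d landmarks, %d GPA iterations\n",
    length(x$ids), x$scheme$k, x$iterations))
  invisible(x)
}

# Deterministic consensus orientation. For symmetric consensus shapes the
# landmark-pair difference vectors are all parallel to the symmetry-plane
# normal; that normal becomes axis 1 and the principal axes of the
# consensus within the plane become axes 2..d. Signs fixed by making the
# largest-|.| coefficient of each axis positive; det corrected to +1 on the
# last axis.
canonical_orientation <- function(consensus, scheme, symmetric) {
  d <- ncol(consensus)
  if (symmetric && nrow(scheme$pairs)) {
    diffs <- consensus[scheme$pairs[, 1], , drop = FALSE] -
      consensus[scheme$pairs[, 2], , drop = FALSE]
    normal <- eigen(crossprod(diffs), symmetric = TRUE)$vectors[, 1]
    proj <- consensus - outer(drop(consensus %*% normal), normal)
    inplane <- eigen(crossprod(proj), symmetric = TRUE)$vectors
    # drop the (numerically zero-variance) direction along the normal
    keep <- order(abs(drop(t(inplane) %*% normal)))[seq_len(d - 1)]
    axes <- cbind(normal, inplane[, sort(keep), drop = FALSE])
  } else {
    axes <- eigen(crossprod(consensus), symmetric = TRUE)$vectors
  }
  for (j in seq_len(d)) {
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) axes[, j] <- -axes[, j]
  }
  if (det(axes) < 0) axes[, d] <- -axes[, d]
  axes
}

# orthogonal projection of unit-size shapes onto the affine tangent plane
# at the (unit-size) consensus
tangent_project <- function(arr, consensus) {
  c_vec <- as.vector(consensus)
  n <- dim(arr)[3]
  for (i in seq_len(n)) {
    x <- as.vector(arr[, , i])
    arr[, , i] <- array(x - sum(x * c_vec) * c_vec + c_vec, dim(consensus))
  }
  arr
}

#' Procrustes distance between two superimposed shapes
#'
#' Root summed squared coordinate difference (partial Procrustes distance)
#' between shapes taken from the same superimposition.
#'
#' @param a,b k x d matrices.
#' @return Non-negative number.
#' @export
procrustes_distance <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("shapes must share landmark scheme")
  sqrt(sum((a - b)^2))
}

#' Procrustes distances from the mean shape
#'
#' @param aligned an `aligned_shapes` object.
#' @param component `"aligned"` (default, the full superimposed
#'   configurations) or `"symmetric"`.
#' @return Named vector of distances to the consensus.
#' @export
distances_to_mean <- function(aligned,
                              component = c("aligned", "symmetric")) {
  component <- match.arg(component)
  arr <- aligned[[component]]
  stats::setNames(
    apply(arr, 3, procrustes_distance, b = aligned$mean_shape),
    aligned$ids)
}

#' Pairwise Procrustes distance matrix
#'
#' @param aligned an `aligned_shapes` object.
#' @inheritParams distances_to_mean
#' @return A `dist` object over specimens.
#' @export
pairwise_distances <- function(aligned,
                               component = c("aligned", "symmetric")) {
  component <- match.arg(component)
  arr <- aligned[[component]]
  flat <- t(apply(arr, 3, as.vector))
  stats::dist(flat)
}

#' Write an aligned shape set to plain-text files
#'
#' Aligned coordinates, symmetric components and sizes go to CSV; the
#' consensus to TPS.
#'
#' @param aligned an `aligned_shapes` object.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_aligned <- function(aligned, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- aligned$scheme
  as_set <- function(arr) new_landmark_set(arr, aligned$ids, sc)
  write_landmarks(as_set(aligned$aligned),
                  file.path(dir, "aligned.csv"), "csv-long")
  write_landmarks(as_set(aligned$symmetric),
                  file.path(dir, "symmetric.csv"), "csv-long")
  utils::write.csv(
    data.frame(specimen_id = aligned$ids,
               centroid_size = aligned$centroid_size,
               log_centroid_size = aligned$log_centroid_size),
    file.path(dir, "sizes.csv"), row.names = FALSE, quote = FALSE)
  con_set <- new_landmark_set(array(aligned$mean_shape,
                                    c(sc$k, sc$dimension, 1)),
                              "consensus", sc)
  write_landmarks(con_set, file.path(dir, "consensus.tps"), "tps")
  invisible(dir)
}
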