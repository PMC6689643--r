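#' Define a landmark scheme
#'
#' A landmark scheme names the landmarks digitized on every specimen and
#' records the object-symmetry structure: which landmarks lie on the sagittal
#' (midline) plane and which form bilateral left/right pairs. The scheme is
#' attached to every landmark set and drives the reflect-and-relabel step of
#' the symmetric/asymmetric decomposition.
#'
#' @param names character vector of landmark labels, in digitizing order.
#' @param midline integer indices (into `names`) of landmarks on the midline
#'   plane.
#' @param pairs two-column integer matrix, one row per bilateral pair
#'   `(left, right)`.
#' @param dimension 2 or 3.
#' @return An object of class `landmark_scheme`.
#' @examples
#' sc <- landmark_scheme(c("a", "b", "c"), midline = 1,
#'                       pairs = rbind(c(2, 3)))
#' sc$k
#' @export
landmark_scheme <- function(names, midline, pairs, dimension = 3) {
  names <- as.character(names)
  k <- length(names)
  if (k < 2L) stop("a scheme needs at least two landmarks")
  if (anyDuplicated(names)) stop("landmark names must be unique")
  if (!dimension %in% c(2L, 3L)) stop("dimension must be 2 or 3")
  midline <- as.integer(midline)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  used <- c(midline, as.vector(pairs))
  if (any(used < 1L | used > k)) stop("landmark index out of range")
  if (any(pairs[, 1] == pairs[, 2])) stop("pair members must be distinct")
  if (anyDuplicated(used) || length(used) != k)
    stop("every landmark must appear exactly once across midline and pairs")
  structure(list(names = names, midline = midline, pairs = pairs,
                 dimension = as.integer(dimension), k = k),
            class = "landmark_scheme")
}

#' @export
print.landmark_scheme <- function(x, ...) {
  cat(sprintf("landmark scheme: %d landmarks (%dD), %d midline, %d pairs\n",
              x$k, x$dimension, length(x$midline), nrow(x$pairs)))
  invisible(x)
}

#' The 28-landmark macaque mandible scheme
#'
#' The standard mandibular landmark set used throughout the package: four
#' midline landmarks (infradentale, mandibular orale, superior transverse
#' torus, gnathion) and twelve bilateral pairs (left indices 5-16 paired with
#' right indices 17-28), covering the corpus, tooth row, gonial region and
#' ramus.
#'
#' @return A `landmark_scheme` with 28 landmarks in 3D.
#' @export
mandible_scheme <- function() {
  nm <- c("infradentale", "mandibular_orale", "superior_transverse_torus",
          "gnathion",
          paste0(c("mental_foramen", "P3_P4_lateral", "M1_M2_lateral",
                   "M3_lateral_posterior", "ramus_anterior", "gonion",
                   "ramus_posterior", "condylion_laterale", "sigmoid_notch",
                   "coronion", "condylion_mediale",
                   "mandibular_foramen_superior"), "_L"),
          paste0(c("mental_foramen", "P3_P4_lateral", "M1_M2_lateral",
                   "M3_lateral_posterior", "ramus_anterior", "gonion",
                   "ramus_posterior", "condylion_laterale", "sigmoid_notch",
                   "coronion", "condylion_mediale",
                   "mandibular_foramen_superior"), "_R"))
  landmark_scheme(nm, midline = 1:4, pairs = cbind(5:16, 17:28),
                  dimension = 3)
}

#' Read or write a landmark scheme as YAML
#'
#' The YAML file has keys `names` (list), `midline` (1-based indices),
#' `pairs` (list of two-element lists) and `dimension`.
#'
#' @param path file path.
#' @return `read_scheme()` returns a `landmark_scheme`.
#' @export
read_scheme <- function(path) {
  y <- yaml::read_yaml(path)
  pairs <- do.call(rbind, lapply(y$pairs, function(p) as.integer(p)))
  landmark_scheme(unlist(y$names), midline = unlist(y$midline),
                  pairs = pairs, dimension = y$dimension)
}

#' @rdname read_scheme
#' @param scheme a `landmark_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  y <- list(names = as.list(scheme$names),
            midline = as.list(scheme$midline),
            pairs = lapply(seq_len(nrow(scheme$pairs)),
                           function(i) as.list(scheme$pairs[i, ])),
            dimension = scheme$dimension)
  yaml::write_yaml(y, path)
  invisible(path)
}

# permutation that maps each landmark to its mirror label (midline fixed)
relabel_permutation <- function(scheme) {
  perm <- seq_len(scheme$k)
  perm[scheme$pairs[, 1]] <- scheme$pairs[, 2]
  perm[scheme$pairs[, 2]] <- scheme$pairs[, 1]
  perm
}

#' Reflect and relabel a configuration
#'
#' Mirrors a configuration through the plane normal to the first coordinate
#' axis (x -> -x) and swaps the left/right landmark labels, leaving midline
#' labels fixed. For a perfectly symmetric configuration oriented with its
#' symmetry plane at x = 0 this is the identity.
#'
#' @param coords k x d coordinate matrix.
#' @param scheme the `landmark_scheme`.
#' @return k x d matrix.
#' @export
reflect_relabel <- function(coords, scheme) {
  out <- coords
  out[, 1] <- -out[, 1]
  out[relabel_permutation(scheme), , drop = FALSE]
}
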