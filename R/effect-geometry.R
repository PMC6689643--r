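#' Extract the effect vector of a predictor over shape responses
#'
#' Collects, for one fixed effect, the posterior draws of its coefficients
#' across all (shape) responses of a multivariate fit — the regression
#' vector whose direction describes how that factor deforms shape. The
#' posterior mean vector is the point estimate used for shape scores.
#'
#' @param fit a `blmm_fit` over shape responses (e.g. PC1..PC10).
#' @param predictor fixed-effect name.
#' @return An `effect_vector`: `predictor`, `beta_draws` (draws x p),
#'   `beta_mean`, `responses`.
#' @export
effect_vector <- function(fit, predictor) {
  p <- match(predictor, fit$fixed)
  if (is.na(p)) stop("predictor not in the model: ", predictor)
  bd <- fit$draws$fixed[, , p, drop = FALSE]
  bd <- matrix(bd, nrow = dim(bd)[1],
               dimnames = list(NULL, fit$responses))
  structure(list(predictor = predictor, beta_draws = bd,
                 beta_mean = colMeans(bd), responses = fit$responses),
            class = "effect_vector")
}

#' @export
print.effect_vector <- function(x, ...) {
  cat(sprintf("effect vector '%s' over %d shape variables (%d draws)\n",
              x$predictor, ncol(x$beta_draws), nrow(x$beta_draws)))
  invisible(x)
}

#' Angle between two vectors
#'
#' Arc-cosine of the cosine similarity, in degrees; 0 for identical
#' directions, 90 for orthogonal, 180 for opposite.
#'
#' @param v,w numeric vectors of equal length.
#' @return Angle in `[0, 180]` degrees.
#' @export
vector_angle <- function(v, w) {
  nv <- sqrt(sum(v^2)); nw <- sqrt(sum(w^2))
  if (nv == 0 || nw == 0) stop("zero vector has no direction")
  acos(max(-1, min(1, sum(v * w) / (nv * nw)))) * 180 / pi
}

#' Element-wise Pearson correlation of two coefficient vectors
#'
#' @param v,w numeric vectors of equal length (>= 3), neither constant.
#' @return Pearson r.
#' @export
vector_correlation <- function(v, w) {
  if (length(v) != length(w)) stop("vectors must have equal length")
  if (length(v) < 3) stop("vector correlation needs length >= 3")
  if (stats::sd(v) == 0 || stats::sd(w) == 0)
    stop("constant vector has no correlation")
  stats::cor(v, w)
}

#' Posterior comparison of two effect directions
#'
#' Compares the directions of shape change attributed to two predictors by
#' propagating posterior uncertainty into the angle and the element-wise
#' correlation between their coefficient vectors.
#'
#' Two modes: `"within"` pairs draw t of `a` with draw t of `b` (effects
#' from the same model fit, sharing draws); `"between"` compares each draw
#' of `a` against the posterior mean vector of `b`, does the same in the
#' opposite direction, and concatenates the two sets (effects from
#' different model fits). The summary flags independence when the 95%
#' interval contains 90 degrees (angle) or 0 (correlation).
#'
#' @param a,b `effect_vector` objects with equal dimension.
#' @param mode `"within"` or `"between"`.
#' @return An `effect_comparison`: `angles`, `correlations` (posterior
#'   samples), and a `summary` data.frame with mean, 95% interval and
#'   independence flag for both measures.
#' @export
compare_effects <- function(a, b, mode = c("within", "between")) {
  mode <- match.arg(mode)
  if (ncol(a$beta_draws) != ncol(b$beta_draws))
    stop("effect vectors live in different dimensions")
  if (mode == "within") {
    if (nrow(a$beta_draws) != nrow(b$beta_draws))
      stop("within-model comparison requires paired draws (equal counts)")
    nt <- nrow(a$beta_draws)
    angles <- vapply(seq_len(nt), function(t)
      vector_angle(a$beta_draws[t, ], b$beta_draws[t, ]), numeric(1))
    cors <- vapply(seq_len(nt), function(t)
      vector_correlation(a$beta_draws[t, ], b$beta_draws[t, ]), numeric(1))
  } else {
    na <- nrow(a$beta_draws); nb <- nrow(b$beta_draws)
    angles <- c(
      vapply(seq_len(na), function(t)
        vector_angle(a$beta_draws[t, ], b$beta_mean), numeric(1)),
      vapply(seq_len(nb), function(t)
        vector_angle(b$beta_draws[t, ], a$beta_mean), numeric(1)))
    cors <- c(
      vapply(seq_len(na), function(t)
        vector_correlation(a$beta_draws[t, ], b$beta_mean), numeric(1)),
      vapply(seq_len(nb), function(t)
        vector_correlation(b$beta_draws[t, ], a$beta_mean), numeric(1)))
  }
  sum_of <- function(x, indep_at) {
    q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
    data.frame(mean = mean(x), lower = q[1], upper = q[2],
               independent = q[1] <= indep_at && indep_at <= q[2])
  }
  smry <- rbind(cbind(measure = "angle", sum_of(angles, 90)),
                cbind(measure = "correlation", sum_of(cors, 0)))
  structure(list(pair = c(a$predictor, b$predictor), mode = mode,
                 angles = angles, correlations = cors, summary = smry),
            class = "effect_comparison")
}

#' @export
print.effect_comparison <- function(x, ...) {
  cat(sprintf("effect comparison %s vs %s (%s-model):\n",
              x$pair[1], x$pair[2], x$mode))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Shape score: projection of shape variables onto an effect direction
#'
#' Computes `s = y beta' (beta beta')^{-1/2}`, i.e. the projection of each
#' specimen's shape variables onto the unit vector along `beta`. The score
#' gives a univariate axis of, e.g., captivity-related shape change; it is
#' invariant to positive rescaling of `beta`.
#'
#' @param y n x p matrix of shape variables on the scale the model was
#'   fitted on.
#' @param beta effect direction: a numeric p-vector or an `effect_vector`
#'   (its posterior mean is used).
#' @return A `shape_score`: `scores` (named n-vector), `beta_used`,
#'   `predictor`.
#' @export
shape_score <- function(y, beta) {
  predictor <- NA_character_
  if (inherits(beta, "effect_vector")) {
    predictor <- beta$predictor
    beta <- beta$beta_mean
  }
  y <- as.matrix(y)
  if (ncol(y) != length(beta))
    stop("shape matrix and beta have mismatched dimensions")
  nb <- sqrt(sum(beta^2))
  if (nb == 0) stop("beta must be non-zero")
  s <- drop(y %*% beta) / nb
  structure(list(scores = stats::setNames(s, rownames(y)),
                 beta_used = beta, predictor = predictor),
            class = "shape_score")
}

#' @export
print.shape_score <- function(x, ...) {
  cat(sprintf("shape score (%s): n = %d, range [%.3f, %.3f]\n",
              if (is.na(x$predictor)) "custom beta" else x$predictor,
              length(x$scores), min(x$scores), max(x$scores)))
  invisible(x)
}

#' Correlation of the shape score with an axis or covariate
#'
#' Pearson correlation (with the usual t-test p-value) between the shape
#' score and a PC axis or any per-specimen covariate, e.g. to check how
#' much of the score is carried by a single PC, or whether it drifts with
#' age or captive generation.
#'
#' @param score a `shape_score` (or numeric vector).
#' @param axis_scores numeric vector of equal length.
#' @return List with `r` and `p_value`.
#' @export
score_axis_correlation <- function(score, axis_scores) {
  s <- if (inherits(score, "shape_score")) score$scores else score
  if (length(s) != length(axis_scores)) stop("inputs must have equal length")
  if (length(s) < 3) stop("correlation needs n >= 3")
  if (stats::sd(s) == 0 || stats::sd(axis_scores) == 0)
    stop("constant input has no correlation")
  ct <- stats::cor.test(s, axis_scores)
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Shape change along the shape score
#'
#' Regresses every landmark coordinate on the shape score and returns the
#' two extreme shapes at plus/minus `magnification` times half the observed
#' score range along the fitted direction — the wireframe pair used to
#' display score-related deformation (an exaggeration factor, e.g. 10, is
#' conventional for small shape effects).
#'
#' @param shapes an `aligned_shapes` (symmetric component) or k x d x n
#'   array of the same specimens the score was computed for.
#' @param score a `shape_score` or numeric vector.
#' @param magnification scale factor on the displayed displacement.
#' @return List with `minus`, `plus` (k x d matrices) and `direction`
#'   (k x d regression slope matrix per unit score).
#' @export
score_shape_change <- function(shapes, score, magnification = 1) {
  s <- if (inherits(score, "shape_score")) score$scores else score
  info <- shape_matrix(shapes, "symmetric")
  if (nrow(info$x) != length(s))
    stop("score and shapes cover different specimen counts")
  if (stats::sd(s) == 0) stop("degenerate score: zero variance")
  yc <- sweep(info$x, 2, colMeans(info$x))
  sc <- s - mean(s)
  slope <- drop(crossprod(yc, sc)) / sum(sc^2)
  consensus <- matrix(colMeans(info$x), info$k, info$d)
  disp <- magnification * diff(range(s)) / 2 *
    matrix(slope, info$k, info$d)
  list(minus = consensus - disp, plus = consensus + disp,
       direction = matrix(slope, info$k, info$d))
}
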