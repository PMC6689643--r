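# shared fixtures: all built in code, no data files

# small symmetric scheme: 2 midline + 3 bilateral pairs, 8 landmarks, 3D
small_scheme <- function() {
  landmark_scheme(
    c("mid_a", "mid_b", paste0(c("p1", "p2", "p3"), "_L"),
      paste0(c("p1", "p2", "p3"), "_R")),
    midline = 1:2, pairs = cbind(3:5, 6:8), dimension = 3)
}

# exactly reflect-relabel symmetric template for small_scheme()
small_template <- function() {
  half <- rbind(c(-2, 3, 0), c(-3, 0, 1), c(-1.5, -2, 2))
  rbind(c(0, 4, 1), c(0, -3, -1), half, half %*% diag(c(-1, 1, 1)))
}

rand_config <- function(k = 8, d = 3) matrix(rnorm(k * d), k, d)

rand_rotation <- function(d = 3) {
  q <- qr.Q(qr(matrix(rnorm(d * d), d, d)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# landmark_set built from a k x d x n array and a scheme
as_landmark_set <- function(coords, scheme,
                            ids = sprintf("s%02d", seq_len(dim(coords)[3]))) {
  dimnames(coords) <- list(scheme$names, c("x", "y", "z")[seq_len(dim(coords)[2])],
                           ids)
  structure(list(coords = coords, ids = ids, scheme = scheme),
            class = "landmark_set")
}

# n noisy similarity-transformed copies of a template
noisy_set <- function(template, scheme, n = 6, noise = 0.05, nuisance = TRUE) {
  k <- nrow(template); d <- ncol(template)
  coords <- array(NA_real_, c(k, d, n))
  for (i in seq_len(n)) {
    cf <- template + matrix(rnorm(k * d, 0, noise), k, d)
    if (nuisance)
      cf <- (cf %*% rand_rotation(d)) * exp(rnorm(1, 0, 0.2)) +
        matrix(rnorm(d, 0, 10), k, d, byrow = TRUE)
    coords[, , i] <- cf
  }
  as_landmark_set(coords, scheme)
}

# independently coded naive GPA (no symmetry, no canonical orientation):
# center + unit-scale, align all to the running mean until stable
naive_gpa <- function(coords) {
  n <- dim(coords)[3]
  x <- coords
  for (i in seq_len(n)) {
    ci <- sweep(coords[, , i], 2, colMeans(coords[, , i]))
    x[, , i] <- ci / sqrt(sum(ci^2))
  }
  ref <- x[, , 1]
  for (rep in 1:3000) {
    for (i in seq_len(n)) {
      s <- svd(t(x[, , i]) %*% ref)
      flip <- diag(c(1, 1, sign(det(s$u %*% t(s$v)))))
      x[, , i] <- x[, , i] %*% (s$u %*% flip %*% t(s$v))
    }
    m <- apply(x, c(1, 2), mean)
    m <- m / sqrt(sum(m^2))
    if (sqrt(mean((m - ref)^2)) < 1e-12) break
    ref <- m
  }
  list(aligned = x, consensus = ref)
}

# tiny metadata table consistent with a landmark_set
toy_metadata <- function(ids, n_pop = 2) {
  n <- length(ids)
  data.frame(specimen_id = ids,
             sex = rep_len(0:1, n), age_class = rep_len(c(1, 1, 0), n),
             captivity = rep_len(0:2, n),
             population = rep_len(sprintf("pop%d", seq_len(n_pop)), n),
             latitude = rep_len(c(31.5, 40.2), n),
             longitude = rep_len(c(130.9, 140.1), n),
             temperature = rep_len(c(18.4, 9.7), n),
             precipitation = rep_len(c(2400, 1300), n))
}

# scaled-down generator settings shared by simulation-heavy tests
quick_sim <- function(seed, n_populations = 8, n_per_population = 12, ...) {
  generate_dataset(synth_config(n_populations = n_populations,
                                n_per_population = n_per_population,
                                seed = seed, ...))
}

# GPA -> PCA -> model frame used by the modelling tests
sim_frame <- function(sim, m = 4) {
  al <- gpa(sim$landmarks)
  pca <- shape_pca(al)
  ret <- retain_pcs(pca, m)
  list(aligned = al, pca = pca,
       frame = data.frame(sim$metadata, size = al$log_centroid_size,
                          ret$scores, check.names = FALSE))
}
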