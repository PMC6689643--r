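test_that("centroid size matches closed forms and scales homogeneously", {
  square <- rbind(c(1, 1), c(1, -1), c(-1, -1), c(-1, 1))
  expect_equal(centroid_size(square), 2 * sqrt(2))
  set.seed(201)
  cfg <- rand_config(28, 3)
  # independent brute-force evaluation of the defining formula
  cen <- colMeans(cfg)
  oracle <- sqrt(sum(sweep(cfg, 2, cen)^2))
  expect_equal(centroid_size(cfg), oracle, tolerance = 1e-12)
  expect_equal(centroid_size(cfg * 3.7), 3.7 * centroid_size(cfg),
               tolerance = 1e-12)
  expect_error(centroid_size(matrix(1, 4, 3)), "coincide")
})

test_that("two-shape OPA recovers rotations exactly and excludes reflections", {
  set.seed(202)
  cfg <- rand_config()
  rot <- rand_rotation()
  fit <- opa_align(cfg %*% rot, cfg)
  expect_lt(fit$residual, 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  # mirror image of a chiral configuration cannot be recovered
  mirror <- cfg %*% diag(c(-1, 1, 1))
  expect_gt(opa_align(mirror, cfg)$residual, 0.05)
  expect_error(opa_align(cbind(1:5, 2 * (1:5), 0), cbind(1:5, 2 * (1:5), 0)),
               "degenerate|rank")
})

test_that("2D OPA residual matches a dense grid search over rotation angles", {
  set.seed(203)
  sc2 <- landmark_scheme(letters[1:6], midline = 1:2,
                         pairs = rbind(c(3, 4), c(5, 6)), dimension = 2)
  a <- matrix(rnorm(12), 6, 2)
  b <- matrix(rnorm(12), 6, 2)
  au <- sweep(a, 2, colMeans(a)); au <- au / sqrt(sum(au^2))
  bu <- sweep(b, 2, colMeans(b)); bu <- bu / sqrt(sum(bu^2))
  grid <- seq(0, 2 * pi, length.out = 200001)
  res <- vapply(grid, function(th) {
    r <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
    sqrt(sum((au %*% r - bu)^2))
  }, numeric(1))
  expect_equal(opa_align(a, b)$residual, min(res), tolerance = 1e-7)
})

test_that("GPA is shape-invariant, matches a naive re-implementation, and is a fixed point", {
  set.seed(204)
  sc <- small_scheme()
  tpl <- small_template()
  # all inputs similarity transforms of one shape -> zero distances
  pure <- noisy_set(tpl, sc, n = 5, noise = 0)
  al <- gpa(pure)
  expect_lt(max(pairwise_distances(al)), 1e-8)

  # consensus and residuals match the independent naive GPA (no symmetry)
  cfgs <- array(rnorm(8 * 3 * 3), c(8, 3, 3))
  al2 <- gpa(as_landmark_set(cfgs, sc), reflect_relabel = FALSE,
             tangent = FALSE)
  nv <- naive_gpa(cfgs)
  # orientation frames differ; compare via rotation-invariant quantities
  expect_equal(as.vector(pairwise_distances(al2)),
               as.vector(dist(t(apply(nv$aligned, 3, as.vector)))),
               tolerance = 1e-8)
  d_my <- apply(al2$aligned, 3, procrustes_distance, b = al2$mean_shape)
  d_nv <- apply(nv$aligned, 3, procrustes_distance, b = nv$consensus)
  expect_equal(unname(d_my), unname(d_nv), tolerance = 1e-8)

  # re-running GPA on aligned output changes nothing
  al3 <- gpa(as_landmark_set(al2$aligned, sc), reflect_relabel = FALSE,
             tangent = FALSE)
  expect_equal(al3$aligned, al2$aligned, tolerance = 1e-9)
})

test_that("object-symmetry decomposition splits shapes exactly", {
  set.seed(205)
  sc <- small_scheme()
  tpl <- small_template()
  # perfectly symmetric specimens: asymmetric component vanishes
  sym_set <- noisy_set(tpl, sc, n = 4, noise = 0)
  al <- gpa(sym_set)
  expect_lt(max(abs(al$asymmetric)), 1e-10)

  # noisy, asymmetric specimens: symmetric part is reflect-relabel
  # invariant and symmetric + asymmetric reconstructs the aligned shape
  noisy <- noisy_set(tpl, sc, n = 6, noise = 0.15)
  al2 <- gpa(noisy)
  for (i in 1:6) {
    s <- al2$symmetric[, , i]
    expect_lt(procrustes_distance(s, reflect_relabel(s, sc)),
              1e-8 * sqrt(sum(s^2)))
    expect_equal(al2$symmetric[, , i] + al2$asymmetric[, , i],
                 al2$aligned[, , i], tolerance = 1e-9)
  }
  expect_gt(max(abs(al2$asymmetric)), 1e-4)
})

test_that("Procrustes distances are metric-like and match pairwise OPA", {
  set.seed(206)
  sc <- small_scheme()
  cfgs <- array(rnorm(72), c(8, 3, 3))
  al <- gpa(as_landmark_set(cfgs, sc), reflect_relabel = FALSE,
            tangent = FALSE)
  a <- al$aligned[, , 1]; b <- al$aligned[, , 2]; c3 <- al$aligned[, , 3]
  expect_equal(procrustes_distance(a, a), 0)
  expect_equal(procrustes_distance(a, b), procrustes_distance(b, a))
  expect_lte(procrustes_distance(a, c3),
             procrustes_distance(a, b) + procrustes_distance(b, c3) + 1e-9)
  # two-shape GPA distance equals the OPA residual of the pair
  two <- gpa(as_landmark_set(cfgs[, , 1:2], sc), reflect_relabel = FALSE,
             tangent = FALSE)
  expect_equal(procrustes_distance(two$aligned[, , 1], two$aligned[, , 2]),
               opa_align(cfgs[, , 1], cfgs[, , 2])$residual,
               tolerance = 1e-8)
})

test_that("distances are invariant to rigid motions and input order", {
  set.seed(207)
  sc <- small_scheme()
  base <- noisy_set(small_template(), sc, n = 5, noise = 0.1,
                    nuisance = FALSE)
  moved <- base
  for (i in 1:5)
    moved$coords[, , i] <- (base$coords[, , i] %*% rand_rotation()) *
      runif(1, 0.5, 2) + matrix(rnorm(3, 0, 20), 8, 3, byrow = TRUE)
  d1 <- pairwise_distances(gpa(base))
  d2 <- pairwise_distances(gpa(moved))
  expect_equal(as.vector(d1), as.vector(d2), tolerance = 1e-8)

  perm <- c(3, 1, 5, 2, 4)
  alp <- gpa(as_landmark_set(base$coords[, , perm], sc))
  dp <- as.matrix(pairwise_distances(alp))
  expect_equal(unname(dp),
               unname(as.matrix(d1)[perm, perm]), tolerance = 1e-9)
})

test_that("aligned shape sets export to plain-text files and read back", {
  set.seed(208)
  sc <- small_scheme()
  al <- gpa(noisy_set(small_template(), sc, n = 4, noise = 0.1))
  dir <- tempfile()
  write_aligned(al, dir)
  expect_true(all(file.exists(file.path(
    dir, c("aligned.csv", "symmetric.csv", "sizes.csv", "consensus.tps")))))
  back <- read_landmarks(file.path(dir, "aligned.csv"), sc)
  expect_equal(unname(back$coords), unname(al$aligned))
})
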