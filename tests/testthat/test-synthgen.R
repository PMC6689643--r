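test_that("generation is bit-reproducible from the seed", {
  cfg <- synth_config(n_populations = 4, n_per_population = 6, seed = 99)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$landmarks$coords, b$landmarks$coords)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth$directions, b$truth$directions)
})

test_that("a pure-nuisance dataset collapses to a single shape after GPA", {
  cfg <- synth_config(n_populations = 3, n_per_population = 4,
                      effect_sizes = c(sex_size = 0, age_size = 0,
                                       allometry_shape = 0, sex_shape = 0,
                                       age_shape = 0, captivity_shape = 0,
                                       temperature_shape = 0),
                      bio_sd_shape = 0, landmark_noise_sd = 0,
                      asymmetry_sd = 0, pop_sd_shape = 0, pop_sd_size = 0,
                      size_noise_sd = 0, nuisance = TRUE, seed = 5)
  sim <- generate_dataset(cfg)
  al <- gpa(sim$landmarks)
  expect_lt(max(pairwise_distances(al)), 1e-8)
})

test_that("asymmetry is controlled by its own noise scale", {
  cfg0 <- synth_config(n_populations = 3, n_per_population = 4,
                       asymmetry_sd = 0, seed = 6)
  al0 <- gpa(generate_dataset(cfg0)$landmarks)
  expect_lt(max(abs(al0$asymmetric)), 1e-8)
  cfg1 <- synth_config(n_populations = 3, n_per_population = 4,
                       asymmetry_sd = 0.3, seed = 6)
  al1 <- gpa(generate_dataset(cfg1)$landmarks)
  expect_gt(max(abs(al1$asymmetric)), 1e-4)
})

test_that("effect directions are orthonormal, symmetric and shape-only", {
  set.seed(701)
  tpl <- sweep(synth_template(), 2, colMeans(synth_template()))
  sc <- mandible_scheme()
  dirs <- synth_effect_directions(tpl, sc, 6)
  expect_lt(max(abs(crossprod(dirs) - diag(6))), 1e-9)
  for (j in 1:6) {
    m <- matrix(dirs[, j], 28, 3)
    # symmetric under reflect-relabel
    expect_lt(max(abs(m - reflect_relabel(m, sc))), 1e-9)
    # orthogonal to translation, rotation and scaling at the template
    expect_lt(abs(sum(m)), 1e-9)                       # translations
    expect_lt(abs(sum(m * tpl)), 1e-9)                 # scaling
    for (ax in list(c(1, 2), c(1, 3), c(2, 3))) {
      g <- matrix(0, 3, 3)
      g[ax[1], ax[2]] <- 1; g[ax[2], ax[1]] <- -1
      expect_lt(abs(sum(m * (tpl %*% g))), 1e-8)       # rotations
    }
  }
})

test_that("metadata structure mirrors the sampling design", {
  sim <- generate_dataset(synth_config(seed = 31))
  meta <- sim$metadata
  expect_equal(nrow(meta), 177)
  expect_equal(length(unique(meta$population)), 23)
  expect_equal(sum(meta$captivity > 0), 93)
  expect_equal(sum(meta$sex), 76)
  expect_equal(sum(meta$age_class == 0), 25)
  expect_true(all(is.na(meta$age_years[meta$captivity == 0])))
  expect_true(all(!is.na(meta$age_years[meta$captivity > 0])))
  expect_true(all(meta$generation[which(meta$captivity == 1)] == 0))
  # ecogeography correlates with latitude as designed
  pops <- meta[!duplicated(meta$population), ]
  expect_lt(cor(pops$latitude, pops$temperature), -0.6)
  # generated files are readable through the package's own readers
  dir <- tempfile()
  sim2 <- generate_dataset(synth_config(n_populations = 3,
                                        n_per_population = 4, seed = 8),
                           dir = dir)
  lm <- read_landmarks(file.path(dir, "landmarks.csv"), mandible_scheme())
  expect_identical(unname(lm$coords), unname(sim2$landmarks$coords))
  expect_equal(read_metadata(file.path(dir, "metadata.csv")),
               sim2$metadata)
})

test_that("a planted captivity direction is recovered by direct regression", {
  # tiny noise, single planted effect: coordinate-wise regression of the
  # aligned symmetric shapes on captivity must recover the direction
  cfg <- synth_config(n_populations = 6, n_per_population = 10,
                      captive_fraction = 0.5,
                      effect_sizes = c(sex_size = 0, age_size = 0,
                                       allometry_shape = 0, sex_shape = 0,
                                       age_shape = 0, captivity_shape = 25,
                                       temperature_shape = 0),
                      bio_sd_shape = 0.02, landmark_noise_sd = 0.02,
                      asymmetry_sd = 0, pop_sd_shape = 0, pop_sd_size = 0,
                      seed = 17)
  sim <- generate_dataset(cfg)
  al <- gpa(sim$landmarks)
  z <- scale(sim$metadata$captivity)[, 1]
  flat <- t(apply(al$symmetric, 3, as.vector))
  slope <- drop(crossprod(sweep(flat, 2, colMeans(flat)), z)) / sum(z^2)
  rot <- opa_align(sim$truth$template, al$mean_shape)$rotation
  planted <- as.vector(matrix(sim$truth$directions[, "captivity"],
                              28, 3) %*% rot)
  expect_lt(vector_angle(slope, planted), 5)
})

test_that("truth_in_pc_space projects through loadings with the right scale", {
  set.seed(702)
  sim <- quick_sim(21, 10, 12)
  al <- gpa(sim$landmarks)
  pca <- shape_pca(al)
  tr <- truth_in_pc_space(sim$truth, pca, m = ncol(pca$scores))
  # projection norms never exceed 1 (directions are unit vectors)
  expect_true(all(tr$pc_coverage <= 1 + 1e-9))
  # full-rank basis captures nearly all of each planted direction
  expect_true(all(tr$pc_coverage > 0.99))
  # hand computation for the captivity row
  rot <- opa_align(sim$truth$template, pca$consensus)$rotation
  v <- as.vector(matrix(sim$truth$directions[, "captivity"], 28, 3) %*% rot)
  hand <- (sim$truth$raw_slopes["captivity"] / sim$truth$template_cs) *
    drop(crossprod(pca$loadings, v)) / apply(pca$scores, 2, sd)
  expect_equal(unname(tr$beta["captivity", ]), unname(hand),
               tolerance = 1e-10)
  # spanning warning fires when too few PCs are kept
  expect_warning(truth_in_pc_space(sim$truth, pca, m = 2), "span")
})
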