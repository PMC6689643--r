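#' The packaged multi-population sampling design
#'
#' A 23-population table of Japanese-macaque sampling localities (wild,
#' captive-source and one mixed population spanning latitudes ~30.3-41.5)
#' with per-population sex and young-adult counts. It is the default design
#' the synthetic generator emulates: uneven population sizes with captivity
#' confounded with a subset of populations.
#'
#' @return data.frame with columns `prefecture`, `population`,
#'   `environment`, `latitude`, `longitude`, `females`, `males`, `total`,
#'   `young_adults`.
#' @export
macaque_populations <- function() {
  utils::read.csv(system.file("extdata", "populations.csv",
                              package = "morphmix"),
                  stringsAsFactors = FALSE)
}

#' A symmetric mandible-like template configuration
#'
#' A hand-built 28-landmark 3D template following the mandibular landmark
#' scheme: four midline points on the symphysis and twelve bilateral pairs
#' along the tooth row, gonial region and ramus. Dimensions are in mm at
#' roughly macaque scale; the configuration is exactly
#' reflect-and-relabel symmetric (midline landmarks on the x = 0 plane,
#' pairs mirrored in x).
#'
#' @return k x d matrix with landmark names as rownames.
#' @export
synth_template <- function() {
  sc <- mandible_scheme()
  half <- rbind(
    mental_foramen              = c(-8, 32, 0),
    P3_P4_lateral               = c(-10, 26, 8),
    M1_M2_lateral               = c(-12, 16, 8),
    M3_lateral_posterior        = c(-14, 6, 8),
    ramus_anterior              = c(-16, 0, 8),
    gonion                      = c(-20, -16, -6),
    ramus_posterior             = c(-21, -18, 6),
    condylion_laterale          = c(-24, -14, 26),
    sigmoid_notch               = c(-18, -8, 22),
    coronion                    = c(-15, -2, 28),
    condylion_mediale           = c(-16, -14, 25),
    mandibular_foramen_superior = c(-14, -8, 6))
  mid <- rbind(infradentale = c(0, 42, 10),
               mandibular_orale = c(0, 40, 8),
               superior_transverse_torus = c(0, 38, 2),
               gnathion = c(0, 41, -6))
  tpl <- rbind(mid, half, half %*% diag(c(-1, 1, 1)))
  rownames(tpl) <- sc$names
  colnames(tpl) <- c("x", "y", "z")
  tpl
}

symmetrize <- function(coords, scheme) (coords + reflect_relabel(coords, scheme)) / 2
antisymmetrize <- function(coords, scheme) (coords - reflect_relabel(coords, scheme)) / 2

# orthonormal basis of the similarity-transform subspace at a centered
# template: d translations, d(d-1)/2 infinitesimal rotations, 1 scaling
similarity_basis <- function(template) {
  k <- nrow(template); d <- ncol(template)
  cen <- center_config(template)
  basis <- list()
  for (j in seq_len(d)) {
    v <- matrix(0, k, d); v[, j] <- 1
    basis[[length(basis) + 1]] <- as.vector(v)
  }
  for (a in seq_len(d - 1)) for (b in (a + 1):d) {
    g <- matrix(0, d, d); g[a, b] <- 1; g[b, a] <- -1
    basis[[length(basis) + 1]] <- as.vector(cen %*% g)
  }
  basis[[length(basis) + 1]] <- as.vector(cen)
  qr.Q(qr(do.call(cbind, basis)))
}

#' Generate planted effect directions
#'
#' Builds mutually orthonormal, reflect-relabel-symmetric deformation
#' fields orthogonal to the similarity-transform subspace at the template,
#' so planted effects survive Procrustes superimposition as genuine shape
#' change rather than being absorbed by translation, rotation or scaling.
#'
#' @param template k x d symmetric template.
#' @param scheme the `landmark_scheme`.
#' @param n_directions number of fields.
#' @return (k*d) x n_directions matrix of unit columns (uses the current
#'   RNG stream).
#' @export
synth_effect_directions <- function(template, scheme, n_directions) {
  k <- nrow(template); d <- ncol(template)
  sim <- similarity_basis(template)
  dirs <- matrix(0, k * d, n_directions)
  for (j in seq_len(n_directions)) {
    v <- as.vector(symmetrize(matrix(stats::rnorm(k * d), k, d), scheme))
    v <- v - sim %*% crossprod(sim, v)
    if (j > 1) {
      prev <- dirs[, seq_len(j - 1), drop = FALSE]
      v <- v - prev %*% crossprod(prev, v)
    }
    dirs[, j] <- v / sqrt(sum(v^2))
  }
  dirs
}

#' Configuration for the synthetic landmark-data generator
#'
#' Defaults are the study conditions the generator emulates: the packaged
#' 23-population sampling design (uneven sizes, captivity confounded with a
#' subset of populations, 177 specimens), standardized effect sizes near
#' the magnitudes reported for macaque mandibles (sex on size 0.7, age
#' class on size 0.2, allometry 0.5, sex on shape 0.5, age on shape 0.2,
#' captivity on shape 0.4, no temperature effect), digitizing-scale
#' landmark noise, modest population heterogeneity, and similarity-
#' transform nuisance on. Setting `n_populations`/`n_per_population`
#' switches to a balanced design for scaled-down simulations.
#'
#' @param n_populations,n_per_population balanced-design size; `NULL`
#'   (default) uses the packaged population table.
#' @param captive_fraction fraction of populations that are captive
#'   (balanced design only).
#' @param sex_ratio probability of male (balanced design only).
#' @param adult_fraction probability of full adulthood (balanced design).
#' @param effect_sizes named vector over `sex_size`, `age_size`,
#'   `allometry_shape`, `sex_shape`, `age_shape`, `captivity_shape`,
#'   `temperature_shape`: slopes per sd of the covariate, in multiples of
#'   the background (non-effect) sd of the trait they act on — the
#'   per-axis biological + noise sd for shape effects, `size_noise_sd`
#'   for size effects — so they read approximately as standardized
#'   coefficients.
#' @param bio_sd_shape sd (mm, along the leading axis) of individual
#'   biological shape variation; variation is spread over `n_bio_axes`
#'   orthogonal symmetric axes with harmonically decaying sds, giving the
#'   low-rank covariance structure (a few dominant PCs) real samples show.
#'   Covariate effects act along the five leading axes.
#' @param n_bio_axes number of biological variation axes.
#' @param landmark_noise_sd isotropic per-coordinate landmark
#'   (digitizing) noise, mm.
#' @param asymmetry_sd per-coordinate sd of the asymmetric (fluctuating)
#'   noise component, mm.
#' @param pop_sd_shape per-coordinate sd of population-level symmetric
#'   shape deviations, mm.
#' @param pop_sd_size sd of population intercepts on log centroid size.
#' @param size_noise_sd residual sd of log centroid size.
#' @param sex_captivity_cos cosine planted between the sex and captivity
#'   shape-change directions: 0 (default) keeps them orthogonal, 1 makes
#'   captivity-related shape change perfectly collinear with sexual
#'   dimorphism (a planted "masculinization" signal).
#' @param nuisance apply a random rotation and translation per specimen.
#' @param template,scheme geometry to deform.
#' @param seed integer seed; generation is bit-reproducible.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_populations = NULL, n_per_population = NULL,
                         captive_fraction = 0.4, sex_ratio = 0.43,
                         adult_fraction = 0.86,
                         effect_sizes = c(sex_size = 0.7, age_size = 0.2,
                                          allometry_shape = 0.5,
                                          sex_shape = 0.5, age_shape = 0.2,
                                          captivity_shape = 0.4,
                                          temperature_shape = 0),
                         bio_sd_shape = 1.4, n_bio_axes = 15,
                         landmark_noise_sd = 0.3, asymmetry_sd = 0.15,
                         pop_sd_shape = 0.12, pop_sd_size = 0.03,
                         size_noise_sd = 0.05, sex_captivity_cos = 0,
                         nuisance = TRUE,
                         template = synth_template(),
                         scheme = mandible_scheme(), seed = 1L) {
  defaults <- c(sex_size = 0.7, age_size = 0.2, allometry_shape = 0.5,
                sex_shape = 0.5, age_shape = 0.2, captivity_shape = 0.4,
                temperature_shape = 0)
  es <- defaults
  es[names(effect_sizes)] <- effect_sizes
  if (any(c(bio_sd_shape, landmark_noise_sd, asymmetry_sd, pop_sd_shape,
            pop_sd_size, size_noise_sd) < 0))
    stop("sds must be non-negative")
  if (n_bio_axes < 5) stop("need at least 5 axes to carry the effects")
  if (sex_captivity_cos < 0 || sex_captivity_cos > 1)
    stop("sex_captivity_cos must be in [0, 1]")
  res <- symmetrize(template, scheme) - template
  if (max(abs(res)) > 1e-8 * max(abs(template)))
    stop("template must be exactly reflect-relabel symmetric")
  structure(list(n_populations = n_populations,
                 n_per_population = n_per_population,
                 captive_fraction = captive_fraction,
                 sex_ratio = sex_ratio, adult_fraction = adult_fraction,
                 effect_sizes = es, bio_sd_shape = bio_sd_shape,
                 n_bio_axes = as.integer(n_bio_axes),
                 landmark_noise_sd = landmark_noise_sd,
                 asymmetry_sd = asymmetry_sd, pop_sd_shape = pop_sd_shape,
                 pop_sd_size = pop_sd_size, size_noise_sd = size_noise_sd,
                 sex_captivity_cos = sex_captivity_cos,
                 nuisance = nuisance, template = template, scheme = scheme,
                 seed = as.integer(seed)),
            class = "synth_config")
}

random_rotation <- function(d) {
  q <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

synth_design <- function(config) {
  if (is.null(config$n_populations)) {
    tab <- macaque_populations()
    rows <- list()
    for (i in seq_len(nrow(tab))) {
      n <- tab$total[i]
      sex <- c(rep(1, tab$males[i]), rep(0, tab$females[i]))
      age <- c(rep(0, tab$young_adults[i]),
               rep(1, n - tab$young_adults[i]))
      env <- tab$environment[i]
      captive <- if (env == "captive") rep(TRUE, n)
        else if (env == "wild") rep(FALSE, n)
        else rep(c(TRUE, FALSE), c(7, n - 7))   # mixed locality
      rows[[i]] <- data.frame(population = tab$population[i],
                              latitude = tab$latitude[i],
                              longitude = tab$longitude[i],
                              sex = sample(sex), age_class = sample(age),
                              captive = sample(captive))
    }
    do.call(rbind, rows)
  } else {
    np <- config$n_populations; npp <- config$n_per_population
    n_cap <- round(config$captive_fraction * np)
    lat <- seq(30.3, 41.5, length.out = np)
    data.frame(population = rep(sprintf("pop%02d", seq_len(np)), each = npp),
               latitude = rep(lat, each = npp),
               longitude = rep(seq(130.4, 141, length.out = np), each = npp),
               sex = stats::rbinom(np * npp, 1, config$sex_ratio),
               age_class = stats::rbinom(np * npp, 1, config$adult_fraction),
               captive = rep(seq_len(np) %in%
                               sample(np, n_cap), each = npp))
  }
}

safe_scale <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
}

#' Generate a synthetic landmark dataset with planted effects
#'
#' Simulates a multi-population sample of bilaterally symmetric landmark
#' configurations: covariates per the sampling design, log centroid size as
#' a linear model in sex and age class with population intercepts, shape as
#' the template plus planted covariate effects along fixed orthonormal
#' symmetric directions, population-level shape deviations, symmetric
#' landmark noise and optional fluctuating asymmetry. Final coordinates are
#' scaled to the specimen's centroid size and, when `nuisance` is on,
#' randomly rotated and translated — the similarity nuisance that
#' Procrustes superimposition must remove.
#'
#' @param config a [synth_config()].
#' @param dir optional directory; when given, writes `landmarks.csv`
#'   (long dialect), `metadata.csv` and `truth.json`.
#' @return List with `landmarks` (a `landmark_set`), `metadata`
#'   (validated data.frame) and `truth` (a `synth_truth` manifest holding
#'   covariates, planted directions and raw coefficients, noise scales,
#'   template and seed).
#' @export
generate_dataset <- function(config, dir = NULL) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$seed)
  sc <- config$scheme
  tpl <- center_config(config$template)
  k <- nrow(tpl); d <- ncol(tpl)
  tpl_cs <- sqrt(sum(tpl^2))
  es <- config$effect_sizes

  n_axes <- config$n_bio_axes
  dirs <- synth_effect_directions(tpl, sc, n_axes)
  colnames(dirs) <- c("size", "sex", "age_class", "captivity",
                      "temperature",
                      if (n_axes > 5) sprintf("bio%02d", 6:n_axes))
  bio_sd <- config$bio_sd_shape / sqrt(seq_len(n_axes))
  cc <- config$sex_captivity_cos
  if (cc > 0)
    dirs[, "captivity"] <- cc * dirs[, "sex"] +
      sqrt(1 - cc^2) * dirs[, "captivity"]

  des <- synth_design(config)
  n <- nrow(des)
  pops <- unique(des$population)
  G <- length(pops)
  gi <- match(des$population, pops)

  # ecogeographic covariates at the population level, correlated with
  # latitude (temperature falls, precipitation falls, going north)
  pop_lat <- des$latitude[match(pops, des$population)]
  pop_temp <- 19.5 - 0.8 * (pop_lat - 30.3) + stats::rnorm(G, 0, 1.5)
  pop_prec <- 2600 - 120 * (pop_lat - 30.3) + stats::rnorm(G, 0, 220)

  captivity <- integer(n)
  founder <- rep(NA, n)
  founder[des$captive] <- stats::runif(sum(des$captive)) < 0.42
  captivity[des$captive] <- ifelse(founder[des$captive], 1L, 2L)
  generation <- rep(NA_integer_, n)
  generation[which(captivity == 1)] <- 0L
  generation[which(captivity == 2)] <-
    sample(1:4, sum(captivity == 2), replace = TRUE)
  age_years <- rep(NA_real_, n)
  nc <- sum(des$captive)
  age_years[des$captive] <- round(pmin(29.5, pmax(6.4,
    stats::rnorm(nc, 14, 5.7))), 1)

  meta <- data.frame(
    specimen_id = sprintf("S%03d", seq_len(n)),
    sex = des$sex, age_class = des$age_class, captivity = captivity,
    population = des$population, latitude = des$latitude,
    longitude = des$longitude,
    temperature = round(pop_temp[gi], 2),
    precipitation = round(pop_prec[gi], 1),
    island = as.integer(des$latitude < 31 | des$population == "Miyajima" |
                          des$population == "Shodoshima"),
    age_years = age_years, generation = generation)

  # log centroid size: planted sex/age effects + population intercepts
  z_sex <- safe_scale(meta$sex); z_age <- safe_scale(meta$age_class)
  u_size <- stats::rnorm(G, 0, config$pop_sd_size)
  lcs <- log(tpl_cs) +
    config$size_noise_sd * (es["sex_size"] * z_sex + es["age_size"] * z_age) +
    u_size[gi] + stats::rnorm(n, 0, config$size_noise_sd)

  z_cap <- safe_scale(meta$captivity)
  z_tmp <- safe_scale(meta$temperature)
  z_lcs <- safe_scale(lcs)
  zmat <- cbind(size = z_lcs, sex = z_sex, age_class = z_age,
                captivity = z_cap, temperature = z_tmp)
  shape_eff <- c(size = unname(es["allometry_shape"]),
                 sex = unname(es["sex_shape"]),
                 age_class = unname(es["age_shape"]),
                 captivity = unname(es["captivity_shape"]),
                 temperature = unname(es["temperature_shape"]))
  # raw slope (mm per covariate sd) relative to the background variation
  # along each effect axis, so effect sizes read as ~standardized slopes
  background_sd <- sqrt(bio_sd[1:5]^2 + config$landmark_noise_sd^2 / 2 +
                          config$pop_sd_shape^2 / 2)
  raw_slopes <- shape_eff * background_sd

  pop_dev <- array(0, c(k, d, G))
  for (g in seq_len(G))
    pop_dev[, , g] <- symmetrize(
      matrix(stats::rnorm(k * d, 0, config$pop_sd_shape), k, d), sc)

  coords <- array(NA_real_, c(k, d, n))
  planted <- dirs[, 1:5, drop = FALSE] %*% (raw_slopes * t(zmat))
  bio_scores <- matrix(stats::rnorm(n * n_axes), n, n_axes) %*%
    diag(bio_sd, n_axes)
  for (i in seq_len(n)) {
    dev <- matrix(planted[, i] + dirs %*% bio_scores[i, ], k, d) +
      pop_dev[, , gi[i]] +
      symmetrize(matrix(stats::rnorm(k * d, 0, config$landmark_noise_sd),
                        k, d), sc)
    if (config$asymmetry_sd > 0)
      dev <- dev + antisymmetrize(
        matrix(stats::rnorm(k * d, 0, config$asymmetry_sd), k, d), sc)
    cfg <- center_config(tpl + dev)
    cfg <- cfg * exp(lcs[i]) / sqrt(sum(cfg^2))
    if (config$nuisance)
      cfg <- cfg %*% random_rotation(d) +
        matrix(stats::rnorm(d, 0, 50), k, d, byrow = TRUE)
    coords[, , i] <- cfg
  }

  landmarks <- new_landmark_set(coords, meta$specimen_id, sc)
  truth <- structure(list(
    covariates = cbind(meta, data.frame(log_centroid_size = lcs)),
    directions = dirs[, 1:5, drop = FALSE], raw_slopes = raw_slopes,
    bio_sd = bio_sd, shape_effects = shape_eff,
    size_effects = c(sex = unname(es["sex_size"]),
                     age_class = unname(es["age_size"])),
    landmark_noise_sd = config$landmark_noise_sd,
    size_noise_sd = config$size_noise_sd,
    pop_size_intercepts = stats::setNames(u_size, pops),
    template = tpl, template_cs = tpl_cs, scheme_k = k, scheme_d = d,
    seed = config$seed), class = "synth_truth")

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_landmarks(landmarks, file.path(dir, "landmarks.csv"), "csv-long")
    write_metadata(meta, file.path(dir, "metadata.csv"))
    jsonlite::write_json(
      list(seed = truth$seed, shape_effects = as.list(truth$shape_effects),
           size_effects = as.list(truth$size_effects),
           landmark_noise_sd = truth$landmark_noise_sd,
           size_noise_sd = truth$size_noise_sd,
           directions = truth$directions),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  list(landmarks = landmarks, metadata = validate_metadata(meta),
       truth = truth)
}

#' Express planted effects as standardized PC-space coefficients
#'
#' Bridges the generator's coordinate-space ground truth to the scale on
#' which the mixed model is fitted: each planted direction is rotated into
#' the superimposition frame (via Procrustes alignment of the template to
#' the PCA consensus), projected through the PC loadings, converted to a
#' per-unit-centroid-size deviation, and standardized by the realized sd of
#' each PC score. The result is directly comparable to the posterior mean
#' coefficients of a standardized fit on the same scores.
#'
#' @param truth a `synth_truth` manifest.
#' @param pca a `shape_pca` fitted on the generated data's symmetric
#'   components.
#' @param m number of leading PCs used as responses.
#' @return List with `beta` (effects x m matrix of true standardized
#'   coefficients), `pc_coverage` (fraction of each direction's norm
#'   captured by the m retained PCs; a warning is recorded below 0.95),
#'   and `size_beta` (true standardized sex/age coefficients on log
#'   centroid size).
#' @export
truth_in_pc_space <- function(truth, pca, m = ncol(pca$scores)) {
  rot <- opa_align(truth$template, pca$consensus)$rotation
  k <- truth$scheme_k; d <- truth$scheme_d
  load_m <- pca$loadings[, seq_len(m), drop = FALSE]
  score_sd <- apply(pca$scores[, seq_len(m), drop = FALSE], 2, stats::sd)
  effects <- names(truth$shape_effects)
  beta <- matrix(0, length(effects), m,
                 dimnames = list(effects, colnames(load_m)))
  cover <- stats::setNames(numeric(length(effects)), effects)
  for (j in seq_along(effects)) {
    v <- as.vector(matrix(truth$directions[, j], k, d) %*% rot)
    proj <- drop(crossprod(load_m, v))
    cover[j] <- sqrt(sum(proj^2)) / sqrt(sum(v^2))
    raw <- truth$raw_slopes[j] / truth$template_cs
    beta[j, ] <- raw * proj / score_sd
  }
  low <- cover < 0.95 & truth$shape_effects != 0
  if (any(low))
    warning("retained PCs span < 95% of planted direction(s): ",
            paste(effects[low], collapse = ", "))
  lcs_sd <- stats::sd(truth$covariates$log_centroid_size)
  size_beta <- truth$size_effects * truth$size_noise_sd / lcs_sd
  list(beta = beta, pc_coverage = cover, size_beta = size_beta)
}
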