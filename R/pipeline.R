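#' Subset specimens by the standard robustness filters
#'
#' Two filters used in captive-wild comparisons: `adults_only` keeps
#' specimens with fully erupted third molars (`age_class == 1`);
#' `exclude_captive_age_over` drops captive specimens older than the given
#' age in years. The age filter applies only to captive specimens — ages of
#' wild specimens are unknown and they are always retained.
#'
#' @param dataset a `morph_dataset`.
#' @param adults_only keep adults only.
#' @param exclude_captive_age_over numeric age threshold (years) or `NULL`.
#' @return The filtered `morph_dataset`.
#' @export
subset_specimens <- function(dataset, adults_only = FALSE,
                             exclude_captive_age_over = NULL) {
  meta <- dataset$metadata
  keep <- rep(TRUE, nrow(meta))
  if (adults_only) keep <- keep & meta$age_class == 1
  if (!is.null(exclude_captive_age_over)) {
    if (!"age_years" %in% names(meta))
      stop("age filter requires an age_years column")
    captive <- meta$captivity > 0
    keep <- keep & !(captive & !is.na(meta$age_years) &
                       meta$age_years > exclude_captive_age_over)
  }
  ids <- meta$specimen_id[keep]
  lm <- new_landmark_set(
    dataset$landmarks$coords[, , match(ids, dataset$landmarks$ids),
                             drop = FALSE],
    ids, dataset$landmarks$scheme)
  structure(list(landmarks = lm,
                 metadata = meta[keep, , drop = FALSE],
                 unmatched = dataset$unmatched),
            class = "morph_dataset")
}

#' Configure the end-to-end analysis pipeline
#'
#' @param simulate a [synth_config()] to generate input data, or `NULL`.
#' @param landmarks,metadata,scheme input file paths (+ scheme) when not
#'   simulating. `landmarks`/`metadata` may also be in-memory objects.
#' @param alpha Grubbs screening level.
#' @param iterative_screen repeat outlier removal until clean.
#' @param m number of principal components retained as shape variables.
#' @param chains,iter,burn MCMC layout for every model fit.
#' @param seed master seed; every stage's seed derives from it.
#' @param ecogeography also fit the ecogeographic models on the wild
#'   subset.
#' @param adults_only,exclude_captive_age_over,island_covariate,
#'   size_adjusted robustness variants of the captivity shape model.
#' @param outdir output directory, or `NULL` to skip writing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = NULL, landmarks = NULL,
                            metadata = NULL, scheme = mandible_scheme(),
                            alpha = 0.05, iterative_screen = FALSE,
                            m = 10, chains = 4, iter = 10000, burn = 5000,
                            seed = 1L, ecogeography = TRUE,
                            adults_only = FALSE,
                            exclude_captive_age_over = NULL,
                            island_covariate = FALSE,
                            size_adjusted = FALSE, outdir = NULL) {
  if (is.null(simulate) && (is.null(landmarks) || is.null(metadata)))
    stop("either a simulate block or landmark + metadata inputs required")
  structure(as.list(environment()), class = "pipeline_config")
}

pipeline_dataset <- function(config) {
  if (!is.null(config$simulate)) {
    sim <- generate_dataset(config$simulate)
    ds <- join_dataset(sim$landmarks, sim$metadata)
    ds$truth <- sim$truth
    return(ds)
  }
  lms <- if (inherits(config$landmarks, "landmark_set")) config$landmarks
    else read_landmarks(config$landmarks, config$scheme)
  meta <- if (is.data.frame(config$metadata)) validate_metadata(config$metadata)
    else read_metadata(config$metadata)
  join_dataset(lms, meta)
}

fit_variant <- function(frame, label, responses, fixed, drop, group,
                        mcmc, seed) {
  full <- blmm(frame, responses, fixed, group = group,
               chains = mcmc$chains, iter = mcmc$iter, burn = mcmc$burn,
               seed = seed)
  reduced <- blmm(frame, responses, setdiff(fixed, drop), group = group,
                  chains = mcmc$chains, iter = mcmc$iter, burn = mcmc$burn,
                  seed = seed + 1L)
  cmp <- compare_models(stats::setNames(list(full, reduced),
                                        paste0(label, c("_full", "_reduced"))))
  cmp$bayes_r2 <- c(bayes_r2(full)$mean, bayes_r2(reduced)$mean)
  list(label = label, full = full, reduced = reduced, comparison = cmp)
}

#' Run the full analysis pipeline
#'
#' Executes the analysis graph end to end: superimposition (GPA with
#' object symmetry), Grubbs outlier screening on distances to the mean
#' shape, re-superimposition of the retained specimens, PCA of the
#' symmetric components with the retention diagnostic, Bayesian mixed
#' model fits for size and shape (captivity test: full vs reduced; and,
#' optionally, the ecogeographic test on the wild subset), WAIC comparison
#' tables, posterior effect-direction comparisons, and the captivity shape
#' score. All randomness derives from `config$seed`; with a fixed seed the
#' written report tables are byte-identical across runs.
#'
#' @param config a [pipeline_config()].
#' @return A `pipeline_report` list (also written to `config$outdir` as
#'   CSV/JSON when set): screening report, PCA summary, model summaries
#'   and WAIC tables, effect comparisons, shape score, run log.
#' @export
run_pipeline <- function(config) {
  stage <- "input"
  report <- list()
  tryCatch({
    dataset <- pipeline_dataset(config)

    stage <- "superimposition"
    al0 <- gpa(dataset$landmarks)

    stage <- "screening"
    screen <- grubbs_screen(distances_to_mean(al0), alpha = config$alpha,
                            iterative = config$iterative_screen,
                            refit = function(keep_ids) {
                              sub <- dataset$landmarks$coords[, , keep_ids,
                                                              drop = FALSE]
                              al <- gpa(new_landmark_set(
                                sub, keep_ids, dataset$landmarks$scheme))
                              distances_to_mean(al)
                            })
    keep <- setdiff(dataset$metadata$specimen_id, screen$outlier_ids)
    meta <- dataset$metadata[match(keep, dataset$metadata$specimen_id), ,
                             drop = FALSE]

    stage <- "re-superimposition"
    al <- gpa(new_landmark_set(
      dataset$landmarks$coords[, , match(keep, dataset$landmarks$ids),
                               drop = FALSE],
      keep, dataset$landmarks$scheme))

    stage <- "pca"
    pca <- shape_pca(al)
    m <- min(config$m, ncol(pca$scores))
    ret <- retain_pcs(pca, m)
    frame <- data.frame(meta, size = al$log_centroid_size[keep],
                        ret$scores, check.names = FALSE)
    pc_names <- colnames(ret$scores)
    if (config$size_adjusted) {
      adj <- size_adjust(al, permutations = 999, seed = config$seed + 7L)
      pca_adj <- shape_pca(adj$residuals)
      m_adj <- min(config$m, ncol(pca_adj$scores))
      frame_adj <- data.frame(meta, size = al$log_centroid_size[keep],
                              pca_adj$scores[, seq_len(m_adj), drop = FALSE],
                              check.names = FALSE)
      report$size_adjustment <- adj[c("r_squared", "p_value")]
    }

    stage <- "models"
    mcmc <- list(chains = config$chains, iter = config$iter,
                 burn = config$burn)
    cap_fixed_shape <- c("size", "sex", "age_class", "captivity")
    if (config$island_covariate) cap_fixed_shape <-
        c(cap_fixed_shape, "island")
    variants <- list(
      fit_variant(frame, "captivity_size", "size",
                  setdiff(cap_fixed_shape, "size"), "captivity",
                  "population", mcmc, config$seed + 10L),
      fit_variant(frame, "captivity_shape", pc_names, cap_fixed_shape,
                  "captivity", "population", mcmc, config$seed + 20L))
    if (config$ecogeography) {
      wild <- frame[frame$captivity == 0, , drop = FALSE]
      eco_fixed <- c("size", "sex", "age_class", "temperature",
                     "precipitation")
      variants <- c(variants, list(
        fit_variant(wild, "ecogeo_size", "size", setdiff(eco_fixed, "size"),
                    c("temperature", "precipitation"), "population", mcmc,
                    config$seed + 30L),
        fit_variant(wild, "ecogeo_shape", pc_names, eco_fixed,
                    c("temperature", "precipitation"), "population", mcmc,
                    config$seed + 40L)))
    }
    if (config$size_adjusted)
      variants <- c(variants, list(
        fit_variant(frame_adj, "captivity_shape_sizeadj",
                    colnames(pca_adj$scores)[seq_len(m_adj)],
                    setdiff(cap_fixed_shape, "size"), "captivity",
                    "population", mcmc, config$seed + 50L)))
    if (config$adults_only || !is.null(config$exclude_captive_age_over)) {
      sub_ids <- subset_specimens(
        structure(list(landmarks = dataset$landmarks, metadata = meta,
                       unmatched = dataset$unmatched),
                  class = "morph_dataset"),
        adults_only = config$adults_only,
        exclude_captive_age_over = config$exclude_captive_age_over
      )$metadata$specimen_id
      frame_sub <- frame[frame$specimen_id %in% sub_ids, , drop = FALSE]
      variants <- c(variants, list(
        fit_variant(frame_sub, "captivity_shape_subset", pc_names,
                    cap_fixed_shape, "captivity", "population", mcmc,
                    config$seed + 60L)))
    }
    names(variants) <- vapply(variants, `[[`, "", "label")

    stage <- "effect-geometry"
    shape_fit <- variants$captivity_shape$full
    preds <- intersect(c("captivity", "sex", "size", "age_class"),
                       shape_fit$fixed)
    vecs <- lapply(preds, effect_vector, fit = shape_fit)
    names(vecs) <- preds
    pairs <- utils::combn(preds, 2, simplify = FALSE)
    comparisons <- list()
    for (pr in pairs) for (md in c("within", "between"))
      comparisons[[paste(pr[1], pr[2], md, sep = ".")]] <-
        compare_effects(vecs[[pr[1]]], vecs[[pr[2]]], mode = md)

    stage <- "shape-score"
    score <- shape_score(shape_fit$Y, vecs$captivity)
    score_cors <- vapply(pc_names, function(pc) {
      score_axis_correlation(score, frame[[pc]])$r
    }, numeric(1))
    shape_change <- score_shape_change(al, score, magnification = 10)

    stage <- "report"
    report$screening <- screen
    report$n_analysed <- length(keep)
    report$pca <- list(
      variance_fraction = pca$variance_fraction,
      retained = m, cumulative_variance = ret$cumulative_variance,
      distance_correlation = ret$distance_correlation)
    report$models <- lapply(variants, function(v)
      list(label = v$label, comparison = v$comparison,
           full_summary = summary(v$full)$parameters,
           reduced_summary = summary(v$reduced)$parameters))
    report$waic_table <- do.call(rbind, c(
      lapply(variants, function(v) v$comparison),
      list(make.row.names = FALSE)))
    report$effect_comparisons <- do.call(rbind, lapply(
      names(comparisons), function(nm) {
        s <- comparisons[[nm]]$summary
        cbind(pair = nm, s)
      }))
    report$comparisons <- comparisons
    report$shape_score <- score
    report$score_pc_correlations <- score_cors
    report$shape_change <- shape_change
    report$fits <- variants
    report$aligned <- al
    report$shape_pca <- pca
    if (!is.null(dataset$truth)) report$truth <- dataset$truth
    report$log <- list(seed = config$seed,
                       mcmc = mcmc, m = m, alpha = config$alpha,
                       package_version =
                         as.character(utils::packageVersion("morphmix")),
                       r_version = paste(R.version$major, R.version$minor,
                                         sep = "."))
    class(report) <- "pipeline_report"
    if (!is.null(config$outdir)) write_report(report, config$outdir)
    report
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf(
    "pipeline report: %d specimens analysed, %d outlier(s), %d PCs retained\n",
    x$n_analysed, length(x$screening$outlier_ids), x$pca$retained))
  print(x$waic_table, row.names = FALSE)
  invisible(x)
}

round_df <- function(df, digits = 6) {
  for (cl in names(df)) if (is.numeric(df[[cl]]))
    df[[cl]] <- round(df[[cl]], digits)
  df
}

#' Write a pipeline report to disk
#'
#' Machine-readable JSON beside CSV tables: screening report, PCA summary,
#' coefficient tables, the WAIC comparison table, effect-direction
#' comparisons, shape scores, and the run log.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_outlier_report(report$screening, file.path(dir, "screening.json"))
  jsonlite::write_json(
    list(pca = report$pca, n_analysed = report$n_analysed,
         score_pc_correlations = as.list(report$score_pc_correlations),
         log = report$log),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = 10)
  utils::write.csv(round_df(report$waic_table),
                   file.path(dir, "waic_table.csv"), row.names = FALSE)
  coef_tab <- do.call(rbind, lapply(report$models, function(mdl) {
    cbind(model = mdl$label, round_df(mdl$full_summary))
  }))
  utils::write.csv(coef_tab, file.path(dir, "coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(round_df(report$effect_comparisons),
                   file.path(dir, "effect_comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(round_df(data.frame(
    specimen_id = names(report$shape_score$scores),
    shape_score = report$shape_score$scores)),
    file.path(dir, "shape_scores.csv"), row.names = FALSE)
  invisible(dir)
}
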