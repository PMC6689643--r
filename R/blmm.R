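#' Standardize model variables
#'
#' Z-scores each named column (mean 0, sd 1) and keeps the centring/scaling
#' record so that fitted quantities can be mapped back to the original
#' scale. All responses and fixed-effect predictors are standardized before
#' model fitting so coefficients are comparable across variables.
#'
#' @param data a data.frame.
#' @param columns character vector of columns to standardize.
#' @return List with `data` (standardized copy), `center`, `scale` (named
#'   vectors).
#' @export
standardize_design <- function(data, columns) {
  center <- scale <- stats::setNames(numeric(length(columns)), columns)
  for (cl in columns) {
    v <- data[[cl]]
    if (is.null(v)) stop("column not found: ", cl)
    if (anyNA(v)) stop("missing values in column: ", cl)
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) stop("zero-variance column: ", cl)
    center[cl] <- mean(v)
    scale[cl] <- s
    data[[cl]] <- (v - center[cl]) / s
  }
  list(data = data, center = center, scale = scale)
}

#' Apply or invert a standardization record
#'
#' @param data data.frame of new values on the original (for `apply`) or
#'   standardized (for `invert`) scale.
#' @param record the list returned by [standardize_design()].
#' @return data.frame on the other scale.
#' @export
apply_standardization <- function(data, record) {
  for (cl in intersect(names(record$center), names(data)))
    data[[cl]] <- (data[[cl]] - record$center[cl]) / record$scale[cl]
  data
}

#' @rdname apply_standardization
#' @export
invert_standardization <- function(data, record) {
  for (cl in intersect(names(record$center), names(data)))
    data[[cl]] <- data[[cl]] * record$scale[cl] + record$center[cl]
  data
}

#' Bayesian Gaussian linear mixed model with group random intercepts
#'
#' Fits, per response r,
#' \deqn{y_{ir} = \alpha_r + x_i'\beta_r + u_{g(i),r} + \epsilon_{ir},\quad
#'   u_{jr} \sim N(0,\tau_r^2),\ \epsilon_{ir} \sim N(0,\sigma_r^2)}
#' with an improper flat prior on the intercept and fixed effects and
#' half-Student-t(`prior_df`, `prior_scale`) priors on the group and
#' residual scales. Multiple responses (e.g. PC1..PC10) are fitted jointly
#' with independent residuals across responses, each response carrying its
#' own group intercepts and scales. Sampling is by a Gibbs scheme: the
#' Gaussian conditionals for coefficients and group levels are conjugate,
#' and the half-t scale priors are handled through their inverse-gamma
#' mixture representation. Pointwise log-likelihoods (summed over responses
#' per observation) are recorded for WAIC.
#'
#' All responses and predictors are z-scored before fitting (see
#' [standardize_design()]); summaries are reported on that scale, matching
#' the convention of reporting comparable standardized coefficients.
#'
#' @param data data.frame holding responses, predictors and the grouping
#'   column.
#' @param responses character vector of response column names.
#' @param fixed character vector of fixed-effect column names (may be
#'   empty).
#' @param group name of the grouping column for random intercepts, or
#'   `NULL` for a model without random effects.
#' @param chains,iter,burn MCMC layout: `chains` chains of `iter`
#'   iterations each, first `burn` discarded.
#' @param seed RNG seed; fits are bit-reproducible given the same seed and
#'   row order.
#' @param prior_df,prior_scale half-Student-t prior on the scales
#'   (defaults: 3 degrees of freedom, scale 2.5 — weakly informative for
#'   unit-sd responses).
#' @param standardize z-score responses and predictors (default TRUE).
#' @param fixed_residual_scale optional known residual sd(s) (scalar or
#'   per response); when given, the residual scale is held fixed instead of
#'   sampled — the conjugate special case used to validate the sampler.
#' @return A `blmm_fit` with draw arrays `fixed` (draws x response x
#'   predictor), `intercept`, `group_levels`, `group_scale`,
#'   `residual_scale`, `pointwise_loglik` (draws x n), `chain` index,
#'   plus the design (`X`, `Y`, `group_index`, `group_names`), the
#'   standardization record, and the model spec.
#' @export
blmm <- function(data, responses, fixed, group = "population",
                 chains = 4, iter = 10000, burn = 5000, seed = 1L,
                 prior_df = 3, prior_scale = 2.5, standardize = TRUE,
                 fixed_residual_scale = NULL) {
  if (!length(responses)) stop("at least one response is required")
  if (burn >= iter) stop("burn-in must be smaller than iter")
  used <- c(responses, fixed)
  miss <- setdiff(used, names(data))
  if (length(miss)) stop("column(s) not in data: ", paste(miss, collapse = ", "))
  if (anyNA(data[, used, drop = FALSE])) stop("missing values in model columns")

  scaling <- NULL
  if (standardize) {
    scaling <- standardize_design(data, unique(used))
    data <- scaling$data
  }
  Y <- as.matrix(data[, responses, drop = FALSE])
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, fixed, drop = FALSE]))
  n <- nrow(Y); R <- ncol(Y); P <- ncol(X)
  if (qr(X)$rank < P) stop("rank-deficient fixed-effect design")

  if (!is.null(group)) {
    if (!group %in% names(data)) stop("grouping column not found: ", group)
    gfac <- factor(data[[group]])
    if (nlevels(gfac) < 2) stop("need at least 2 groups for random intercepts")
    gi <- as.integer(gfac)
    gnames <- levels(gfac)
    G <- nlevels(gfac)
    ng <- tabulate(gi, G)
  } else {
    gi <- NULL; gnames <- character(0); G <- 0L; ng <- integer(0)
  }

  XtXinv <- chol2inv(chol(crossprod(X)))
  rchol <- t(chol(XtXinv))          # B = Bhat + rchol %*% N(0,1) * sigma
  nu <- prior_df; A2 <- prior_scale^2
  sig_fixed <- !is.null(fixed_residual_scale)
  if (sig_fixed) {
    sigma <- rep_len(fixed_residual_scale, R)
    if (any(sigma <= 0)) stop("fixed residual scale must be positive")
  }

  keep <- iter - burn
  td <- chains * keep
  fixed_names <- colnames(X)[-1]
  draws <- list(
    fixed = array(NA_real_, c(td, R, P - 1),
                  dimnames = list(NULL, responses, fixed_names)),
    intercept = matrix(NA_real_, td, R, dimnames = list(NULL, responses)),
    group_levels = if (G) array(NA_real_, c(td, R, G),
                                dimnames = list(NULL, responses, gnames)),
    group_scale = if (G) matrix(NA_real_, td, R,
                                dimnames = list(NULL, responses)),
    residual_scale = matrix(NA_real_, td, R, dimnames = list(NULL, responses)),
    pointwise_loglik = matrix(NA_real_, td, n),
    chain = rep(seq_len(chains), each = keep))

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  Bhat0 <- XtXinv %*% crossprod(X, Y)
  res0 <- Y - X %*% Bhat0
  s20 <- pmax(colMeans(res0^2), 1e-8)

  row0 <- 0L
  for (ch in seq_len(chains)) {
    # overdispersed inits across chains
    B <- Bhat0 + rchol %*% matrix(stats::rnorm(P * R), P, R) *
      rep(sqrt(s20), each = P)
    sigma2 <- if (sig_fixed) sigma^2 else s20 * exp(stats::runif(R, -0.5, 0.5))
    tau2 <- s20 * exp(stats::runif(R, -1, 0.5))
    a_sig <- a_tau <- rep(1, R)
    U <- if (G) matrix(0, G, R) else NULL

    for (t in seq_len(iter)) {
      # fixed effects | rest (flat prior, conjugate Gaussian)
      Ru <- if (G) Y - U[gi, , drop = FALSE] else Y
      Bhat <- XtXinv %*% crossprod(X, Ru)
      B <- Bhat + rchol %*% matrix(stats::rnorm(P * R), P, R) *
        rep(sqrt(sigma2), each = P)
      Fv <- X %*% B
      E <- Y - Fv
      if (G) {
        # group levels | rest
        S <- rowsum(E, gi)
        prec <- outer(ng, 1 / sigma2) + rep(1 / tau2, each = G)
        mu_u <- (S / rep(sigma2, each = G)) / prec
        U <- mu_u + matrix(stats::rnorm(G * R), G, R) / sqrt(prec)
        resid <- E - U[gi, , drop = FALSE]
        # group scale | levels (half-t via inverse-gamma mixture)
        ssu <- colSums(U^2)
        tau2 <- 1 / stats::rgamma(R, (nu + G) / 2, rate = nu / a_tau + ssu / 2)
        a_tau <- 1 / stats::rgamma(R, (nu + 1) / 2, rate = nu / tau2 + 1 / A2)
      } else resid <- E
      if (!sig_fixed) {
        ssr <- colSums(resid^2)
        sigma2 <- 1 / stats::rgamma(R, (nu + n) / 2, rate = nu / a_sig + ssr / 2)
        a_sig <- 1 / stats::rgamma(R, (nu + 1) / 2, rate = nu / sigma2 + 1 / A2)
      }
      if (t > burn) {
        row0 <- row0 + 1L
        draws$fixed[row0, , ] <- t(B[-1, , drop = FALSE])
        draws$intercept[row0, ] <- B[1, ]
        if (G) {
          draws$group_levels[row0, , ] <- t(U)
          draws$group_scale[row0, ] <- sqrt(tau2)
        }
        draws$residual_scale[row0, ] <- sqrt(sigma2)
        M <- if (G) Fv + U[gi, , drop = FALSE] else Fv
        ll <- stats::dnorm(Y, M, rep(sqrt(sigma2), each = n), log = TRUE)
        draws$pointwise_loglik[row0, ] <- rowSums(ll)
      }
    }
  }
  if (any(!is.finite(draws$pointwise_loglik)))
    stop("non-finite state encountered during sampling")

  structure(list(draws = draws, responses = responses, fixed = fixed_names,
                 group = group, group_names = gnames, X = X, Y = Y,
                 group_index = gi, n = n, chains = chains, iter = iter,
                 burn = burn, seed = seed, scaling = scaling,
                 prior = list(df = prior_df, scale = prior_scale),
                 ids = rownames(data)),
            class = "blmm_fit")
}

#' @export
print.blmm_fit <- function(x, ...) {
  cat(sprintf(
    "Bayesian LMM: %d response(s) ~ %s%s; %d obs, %d draws (%d chains)\n",
    length(x$responses),
    if (length(x$fixed)) paste(x$fixed, collapse = " + ") else "1",
    if (!is.null(x$group)) paste0(" + (1 | ", x$group, ")") else "",
    x$n, nrow(x$draws$residual_scale), x$chains))
  invisible(x)
}

# draws x parameter matrix over all scalar parameters, named
flatten_draws <- function(fit) {
  d <- fit$draws
  out <- list()
  for (r in seq_along(fit$responses)) {
    rn <- fit$responses[r]
    out[[paste0("Intercept_", rn)]] <- d$intercept[, r]
    for (p in seq_along(fit$fixed))
      out[[paste0("b_", rn, "_", fit$fixed[p])]] <- d$fixed[, r, p]
    if (!is.null(fit$group)) out[[paste0("sd_group_", rn)]] <- d$group_scale[, r]
    out[[paste0("sigma_", rn)]] <- d$residual_scale[, r]
  }
  do.call(cbind, out)
}

#' Split-chain potential scale reduction (Rhat)
#'
#' Computes the split-chain Rhat convergence diagnostic: each chain is cut
#' in half and the between- to within-sequence variance ratio compared.
#' Values near 1 indicate convergence; values above 1.1 are conventionally
#' taken as a warning.
#'
#' @param x a `blmm_fit`, or a numeric matrix of draws with one column per
#'   chain.
#' @param parameter for a fit: the flattened parameter name (e.g.
#'   `"b_PC1_captivity"`); omit to get all Rhats.
#' @return A single Rhat, or a named vector over parameters.
#' @export
rhat <- function(x, parameter = NULL) {
  if (inherits(x, "blmm_fit")) {
    fm <- flatten_draws(x)
    per_chain <- function(v) matrix(v, ncol = x$chains)
    if (is.null(parameter))
      return(vapply(colnames(fm),
                    function(p) split_rhat(per_chain(fm[, p])), numeric(1)))
    if (!parameter %in% colnames(fm)) stop("unknown parameter: ", parameter)
    return(split_rhat(per_chain(fm[, parameter])))
  }
  split_rhat(as.matrix(x))
}

split_rhat <- function(chain_matrix) {
  l <- nrow(chain_matrix)
  if (ncol(chain_matrix) < 2 || l < 4)
    stop("Rhat needs >= 2 chains with >= 4 draws each")
  half <- floor(l / 2)
  seqs <- cbind(chain_matrix[seq_len(half), , drop = FALSE],
                chain_matrix[(l - half + 1):l, , drop = FALSE])
  w <- mean(apply(seqs, 2, stats::var))
  b <- half * stats::var(colMeans(seqs))
  if (w <= .Machine$double.eps && b <= .Machine$double.eps) return(1)
  sqrt(((half - 1) / half * w + b / half) / w)
}

#' Widely applicable information criterion (WAIC)
#'
#' From the pointwise log-likelihood draws:
#' `lppd_i = log mean_t exp(logL_it)`, `p_i = var_t(logL_it)`,
#' `WAIC = -2 * sum(lppd_i - p_i)`. The standard error is
#' `sqrt(n) * sd` of the pointwise contributions. Smaller is better.
#'
#' @param fit a `blmm_fit` (or a draws x observations log-likelihood
#'   matrix).
#' @return List with `waic`, `se`, `p_waic`, `lppd`, and the `pointwise`
#'   table.
#' @export
waic <- function(fit) {
  ll <- if (inherits(fit, "blmm_fit")) fit$draws$pointwise_loglik
        else as.matrix(fit)
  if (any(!is.finite(ll))) stop("non-finite pointwise log-likelihood")
  s <- nrow(ll)
  # stable log mean exp per observation
  mx <- apply(ll, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(ll, 2, mx))))
  p_i <- apply(ll, 2, stats::var)
  elpd_i <- lppd_i - p_i
  waic_i <- -2 * elpd_i
  n <- ncol(ll)
  list(waic = sum(waic_i), se = sqrt(n) * stats::sd(waic_i),
       p_waic = sum(p_i), lppd = sum(lppd_i),
       pointwise = data.frame(lppd = lppd_i, p_waic = p_i, waic = waic_i))
}

#' Compare models by WAIC
#'
#' Computes WAIC for each fit and the difference to the smallest-WAIC
#' model, with the paired standard error of the difference
#' (`sqrt(n) * sd` of pointwise WAIC differences). The best model's delta
#' columns are left `NA`, mirroring the usual blank cell in comparison
#' tables.
#'
#' @param ... named `blmm_fit` objects, or a single named list of them.
#' @return data.frame with `model`, `waic`, `se`, `delta_waic`,
#'   `delta_se`, ordered as given.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "blmm_fit")) fits <- fits[[1]]
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    names(fits) <- sprintf("model_%d", seq_along(fits))
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1)
    stop("models must be fitted to the same observations")
  ws <- lapply(fits, waic)
  totals <- vapply(ws, function(w) w$waic, numeric(1))
  best <- which.min(totals)
  n <- ns[1]
  delta <- delta_se <- rep(NA_real_, length(fits))
  for (i in seq_along(fits)) {
    if (i == best) next
    dw <- ws[[i]]$pointwise$waic - ws[[best]]$pointwise$waic
    delta[i] <- sum(dw)
    delta_se[i] <- sqrt(n) * stats::sd(dw)
  }
  data.frame(model = names(fits), waic = totals,
             se = vapply(ws, function(w) w$se, numeric(1)),
             delta_waic = delta, delta_se = delta_se,
             row.names = NULL)
}

#' Bayes R-squared
#'
#' Per posterior draw, the variance of the fitted values (including group
#' levels) over that variance plus the residual variance; for multivariate
#' fits the ratio is averaged over responses within each draw. Reported as
#' the posterior mean with a 95% interval.
#'
#' @param fit a `blmm_fit`.
#' @return List with `mean`, `lower`, `upper`, and the per-draw values.
#' @export
bayes_r2 <- function(fit) {
  d <- fit$draws
  td <- nrow(d$residual_scale)
  R <- length(fit$responses)
  vals <- numeric(td)
  for (t in seq_len(td)) {
    B <- rbind(d$intercept[t, ], matrix(d$fixed[t, , ],
                                        nrow = length(fit$fixed),
                                        byrow = TRUE))
    M <- fit$X %*% B
    if (!is.null(fit$group))
      M <- M + t(matrix(d$group_levels[t, , ], nrow = R))[fit$group_index, ,
                                                          drop = FALSE]
    vf <- apply(M, 2, stats::var)
    vals[t] <- mean(vf / (vf + d$residual_scale[t, ]^2))
  }
  qs <- stats::quantile(vals, c(0.025, 0.975), names = FALSE)
  list(mean = mean(vals), lower = qs[1], upper = qs[2], draws = vals)
}

#' Posterior summary of a fitted model
#'
#' Posterior mean, sd, 95% credible interval and split-chain Rhat for every
#' scalar parameter, plus WAIC and Bayes R-squared. A note is attached when
#' any Rhat is at or above 1.1.
#'
#' @param object a `blmm_fit`.
#' @param ... unused.
#' @return A `blmm_summary`: list with `parameters` (data.frame), `waic`,
#'   `bayes_r2`, `max_rhat`, `converged`.
#' @export
summary.blmm_fit <- function(object, ...) {
  fm <- flatten_draws(object)
  rh <- rhat(object)
  qs <- t(apply(fm, 2, stats::quantile, probs = c(0.025, 0.975)))
  pars <- data.frame(parameter = colnames(fm), mean = colMeans(fm),
                     sd = apply(fm, 2, stats::sd),
                     lower = qs[, 1], upper = qs[, 2],
                     rhat = rh[colnames(fm)], row.names = NULL)
  w <- waic(object)
  r2 <- bayes_r2(object)
  structure(list(parameters = pars, waic = w$waic, waic_se = w$se,
                 bayes_r2 = r2$mean, max_rhat = max(pars$rhat),
                 converged = max(pars$rhat) < 1.1),
            class = "blmm_summary")
}

#' @export
print.blmm_summary <- function(x, ...) {
  pars <- x$parameters
  pars[, -1] <- round(pars[, -1], 3)
  print(pars, row.names = FALSE)
  cat(sprintf("WAIC %.1f (se %.1f)   Bayes R2 %.3f   max Rhat %.3f%s\n",
              x$waic, x$waic_se, x$bayes_r2, x$max_rhat,
              if (!x$converged) "  [WARNING: Rhat >= 1.1]" else ""))
  invisible(x)
}

#' Marginal effect of one predictor
#'
#' Posterior fitted response at chosen levels of a focal predictor, with
#' all other predictors held at their means and random effects at zero.
#' Levels are given on the original data scale and results returned on the
#' original response scale (when the fit was standardized).
#'
#' @param fit a `blmm_fit`.
#' @param focal name of the focal fixed effect.
#' @param levels numeric values of the focal predictor (original scale).
#' @param response response name (default: first response).
#' @return data.frame with `level`, `mean`, `lower`, `upper`.
#' @export
marginal_effect <- function(fit, focal, levels, response = NULL) {
  if (!focal %in% fit$fixed) stop("focal predictor not in the model: ", focal)
  if (is.null(response)) response <- fit$responses[1]
  r <- match(response, fit$responses)
  if (is.na(r)) stop("unknown response: ", response)
  sc <- fit$scaling
  z <- if (!is.null(sc) && focal %in% names(sc$center))
    (levels - sc$center[focal]) / sc$scale[focal] else levels
  obs <- fit$X[, focal]
  if (any(z < min(obs) - 1e-9 | z > max(obs) + 1e-9))
    warning("requested level(s) outside the observed range of ", focal)
  p <- match(focal, fit$fixed)
  draws_mat <- outer(fit$draws$fixed[, r, p], z) + fit$draws$intercept[, r]
  out <- data.frame(
    level = levels,
    mean = colMeans(draws_mat),
    lower = apply(draws_mat, 2, stats::quantile, 0.025),
    upper = apply(draws_mat, 2, stats::quantile, 0.975))
  if (!is.null(sc) && response %in% names(sc$center)) {
    for (cl in c("mean", "lower", "upper"))
      out[[cl]] <- out[[cl]] * sc$scale[response] + sc$center[response]
  }
  rownames(out) <- NULL
  out
}

#' Persist posterior draws as a columnar CSV
#'
#' One row per draw with chain index; columns are the flattened parameter
#' names of [rhat()]/[summary.blmm_fit()].
#'
#' @param fit a `blmm_fit`.
#' @param path output CSV.
#' @export
write_draws <- function(fit, path) {
  fm <- flatten_draws(fit)
  df <- data.frame(chain = fit$draws$chain,
                   draw = sequence(rep(nrow(fm) / fit$chains, fit$chains)),
                   fm, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
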