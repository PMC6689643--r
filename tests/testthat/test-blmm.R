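test_that("standardization is exact, invertible, and rejects constants", {
  df <- data.frame(a = c(0, 1, 1, 0, 1), b = c(0, 1, 2, 2, 1),
                   c = rep(3, 5))
  st <- standardize_design(df, c("a", "b"))
  for (cl in c("a", "b")) {
    expect_lt(abs(mean(st$data[[cl]])), 1e-12)
    expect_lt(abs(sd(st$data[[cl]]) - 1), 1e-12)
  }
  # captivity-style codes against the hand formula
  expect_equal(st$data$b, (df$b - mean(df$b)) / sd(df$b))
  back <- invert_standardization(st$data, st)
  expect_equal(back$a, df$a, tolerance = 1e-12)
  expect_equal(back$b, df$b, tolerance = 1e-12)
  new <- apply_standardization(data.frame(b = c(0, 4)), st)
  expect_equal(new$b, (c(0, 4) - mean(df$b)) / sd(df$b))
  expect_error(standardize_design(df, "c"), "zero-variance.*c")
})

test_that("the Gibbs sampler reproduces the conjugate closed form", {
  set.seed(501)
  n <- 60
  x1 <- rnorm(n); x2 <- rnorm(n)
  sigma <- 0.8
  y <- 1 + 0.9 * x1 - 0.4 * x2 + rnorm(n, 0, sigma)
  df <- data.frame(y = y, x1 = x1, x2 = x2)
  fit <- blmm(df, "y", c("x1", "x2"), group = NULL, chains = 4,
              iter = 2000, burn = 500, seed = 7, standardize = FALSE,
              fixed_residual_scale = sigma)
  # with known sigma, no random effect and a flat prior the posterior is
  # exactly N(bhat, sigma^2 (X'X)^-1)
  X <- cbind(1, x1, x2)
  xtxi <- solve(crossprod(X))
  bhat <- drop(xtxi %*% crossprod(X, y))
  true_sd <- sigma * sqrt(diag(xtxi))
  draws <- cbind(fit$draws$intercept[, 1], fit$draws$fixed[, 1, ])
  td <- nrow(draws)
  for (j in 1:3) {
    mcse <- sd(draws[, j]) / sqrt(td / 10)  # conservative ESS guess
    expect_lt(abs(mean(draws[, j]) - bhat[j]), 3 * mcse + 1e-12)
    expect_lt(abs(sd(draws[, j]) - true_sd[j]), 3 * true_sd[j] / sqrt(td / 10))
  }
  expect_lt(max(rhat(fit)), 1.1)
})

test_that("duplicated responses give exchangeable posterior summaries", {
  set.seed(502)
  n <- 50
  df <- data.frame(y1 = rnorm(n), x = rnorm(n),
                   g = rep(letters[1:5], each = 10))
  df$y1 <- df$y1 + 0.5 * df$x
  df$y2 <- df$y1
  fit <- blmm(df, c("y1", "y2"), "x", group = "g", chains = 2,
              iter = 1200, burn = 400, seed = 3)
  m1 <- mean(fit$draws$fixed[, "y1", "x"])
  m2 <- mean(fit$draws$fixed[, "y2", "x"])
  mcse <- sd(fit$draws$fixed[, "y1", "x"]) / sqrt(400)
  expect_lt(abs(m1 - m2), 4 * mcse)
})

test_that("fits are bit-reproducible under a fixed seed", {
  set.seed(503)
  df <- data.frame(y = rnorm(30), x = rnorm(30),
                   g = rep(c("a", "b", "c"), 10))
  f1 <- blmm(df, "y", "x", group = "g", chains = 2, iter = 300, burn = 100,
             seed = 11)
  f2 <- blmm(df, "y", "x", group = "g", chains = 2, iter = 300, burn = 100,
             seed = 11)
  expect_identical(f1$draws$fixed, f2$draws$fixed)
  expect_identical(f1$draws$pointwise_loglik, f2$draws$pointwise_loglik)
})

test_that("split-Rhat matches the textbook formula and flags divergence", {
  set.seed(504)
  # fixed small draw array: independently coded split-Rhat
  cm <- matrix(rnorm(40), 10, 4)
  half <- 5
  seqs <- cbind(cm[1:5, ], cm[6:10, ])
  w <- mean(apply(seqs, 2, var))
  b <- half * var(colMeans(seqs))
  oracle <- sqrt(((half - 1) / half * w + b / half) / w)
  expect_equal(rhat(cm), oracle, tolerance = 1e-12)

  same <- matrix(rnorm(4000), 1000, 4)
  expect_lt(abs(rhat(same) - 1), 0.05)
  apart <- cbind(rnorm(500), rnorm(500) + 10)
  expect_gt(rhat(apart), 1.1)
})

test_that("WAIC matches brute-force recomputation and its degenerate limit", {
  set.seed(505)
  ll <- matrix(rnorm(200 * 7, -2, 0.3), 200, 7)
  w <- waic(ll)
  lppd <- sum(log(colMeans(exp(ll))))
  p <- sum(apply(ll, 2, var))
  expect_equal(w$waic, -2 * (lppd - p), tolerance = 1e-10)
  expect_equal(w$se, sqrt(7) * sd(-2 * (log(colMeans(exp(ll))) -
                                          apply(ll, 2, var))),
               tolerance = 1e-10)
  # all draws identical: p_waic = 0, WAIC = -2 * sum log density
  ll0 <- matrix(rep(c(-1.3, -0.7, -2.1), each = 50), 50, 3)
  w0 <- waic(ll0)
  expect_equal(w0$p_waic, 0)
  expect_equal(w0$waic, -2 * sum(c(-1.3, -0.7, -2.1)))
  expect_error(waic(matrix(c(-1, Inf), 1, 2)), "non-finite")
})

test_that("model comparison reproduces per-model WAIC and paired errors", {
  set.seed(506)
  df <- data.frame(y = rnorm(36), x = rnorm(36), g = rep(letters[1:4], 9))
  df$y <- df$y + 0.8 * df$x
  f1 <- blmm(df, "y", "x", group = "g", chains = 2, iter = 600, burn = 200,
             seed = 1)
  f0 <- blmm(df, "y", character(0), group = "g", chains = 2, iter = 600,
             burn = 200, seed = 2)
  cmp <- compare_models(full = f1, reduced = f0)
  expect_equal(cmp$waic, c(waic(f1)$waic, waic(f0)$waic))
  best <- which.min(cmp$waic)
  expect_true(is.na(cmp$delta_waic[best]))
  other <- setdiff(1:2, best)
  # paired se by hand from the pointwise tables
  dw <- waic(list(f1, f0)[[other]])$pointwise$waic -
    waic(list(f1, f0)[[best]])$pointwise$waic
  expect_equal(cmp$delta_waic[other], sum(dw), tolerance = 1e-10)
  expect_equal(cmp$delta_se[other], sqrt(36) * sd(dw), tolerance = 1e-10)
  # self-comparison: delta zero with zero error
  cmp2 <- compare_models(a = f1, b = f1)
  expect_equal(cmp2$delta_waic[2], 0)
  expect_equal(cmp2$delta_se[2], 0)
})

test_that("Bayes R2 separates signal from noise and matches a hand formula", {
  set.seed(507)
  n <- 80
  x <- rnorm(n)
  g <- rep(letters[1:4], n / 4)
  strong <- data.frame(y = 2 * x + rnorm(n, 0, 0.05), x = x, g = g)
  weak <- data.frame(y = rnorm(n), x = x, g = g)
  fs <- blmm(strong, "y", "x", group = "g", chains = 2, iter = 800,
             burn = 300, seed = 4)
  fw <- blmm(weak, "y", "x", group = "g", chains = 2, iter = 800,
             burn = 300, seed = 5)
  expect_gt(bayes_r2(fs)$mean, 0.95)
  expect_lt(bayes_r2(fw)$mean, 0.25)
  # hand recomputation for a single draw
  r2 <- bayes_r2(fs)
  t1 <- 1
  b <- c(fs$draws$intercept[t1, 1], fs$draws$fixed[t1, 1, 1])
  fitted <- fs$X %*% b + fs$draws$group_levels[t1, 1, ][fs$group_index]
  hand <- var(drop(fitted)) /
    (var(drop(fitted)) + fs$draws$residual_scale[t1, 1]^2)
  expect_equal(r2$draws[t1], unname(hand), tolerance = 1e-10)
})

test_that("marginal effects track the coefficient and match a draw-wise oracle", {
  set.seed(508)
  n <- 70
  x <- rnorm(n); z <- rnorm(n)
  df <- data.frame(y = 0.6 * x - 0.2 * z + rnorm(n, 0, 0.3), x = x, z = z,
                   g = rep(c("p", "q"), n / 2))
  fit <- blmm(df, "y", c("x", "z"), group = "g", chains = 2, iter = 800,
              burn = 300, seed = 6)
  lv <- quantile(x, c(0.2, 0.5, 0.8), names = FALSE)
  me <- marginal_effect(fit, "x", lv, "y")
  # draw-wise oracle on the standardized scale, then destandardized
  sc <- fit$scaling
  zlv <- (lv - sc$center["x"]) / sc$scale["x"]
  oracle <- vapply(zlv, function(l)
    mean(fit$draws$intercept[, 1] + fit$draws$fixed[, 1, "x"] * l),
    numeric(1)) * sc$scale["y"] + sc$center["y"]
  expect_equal(me$mean, unname(oracle), tolerance = 1e-10)
  # profile slope recovers the generating coefficient
  slope <- (me$mean[3] - me$mean[1]) / (lv[3] - lv[1])
  expect_lt(abs(slope - 0.6), 0.15)
  expect_warning(marginal_effect(fit, "x", max(x) + 5, "y"), "outside")
})

test_that("permuting observations leaves posterior summaries unchanged", {
  set.seed(509)
  n <- 48
  df <- data.frame(y = rnorm(n), x = rnorm(n), g = rep(letters[1:4], n / 4))
  df$y <- df$y + 0.7 * df$x
  fit1 <- blmm(df, "y", "x", group = "g", chains = 2, iter = 1000,
               burn = 400, seed = 8)
  perm <- sample(n)
  fit2 <- blmm(df[perm, ], "y", "x", group = "g", chains = 2, iter = 1000,
               burn = 400, seed = 9)
  s1 <- summary(fit1)$parameters
  s2 <- summary(fit2)$parameters
  expect_equal(s1$mean, s2$mean, tolerance = 0.08)
})

test_that("degenerate designs are rejected with clear messages", {
  df <- data.frame(y = rnorm(20), x = rnorm(20), x2 = 0,
                   g = rep(c("a", "b"), 10))
  expect_error(blmm(df, "y", "x2", group = "g", iter = 100, burn = 50),
               "zero-variance")
  df$x3 <- df$x
  expect_error(blmm(df, "y", c("x", "x3"), group = "g", iter = 100,
                    burn = 50, standardize = FALSE), "rank-deficient")
  expect_error(blmm(df, "y", "x", group = "g", iter = 100, burn = 200),
               "burn-in")
})
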