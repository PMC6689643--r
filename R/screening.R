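#' Grubbs critical value (one-sided)
#'
#' Critical value of the one-sided (upper) Grubbs test at level `alpha` for
#' sample size `n`, from the Student-t quantile:
#' \deqn{G_{crit} = \frac{n-1}{\sqrt n}\sqrt{\frac{t^2}{n-2+t^2}},\quad
#'       t = t_{\alpha/n,\,n-2}}
#'
#' @param n sample size (>= 3).
#' @param alpha significance level.
#' @return The critical value.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  if (n < 3) stop("Grubbs test needs n >= 3")
  t2 <- stats::qt(alpha / n, df = n - 2, lower.tail = FALSE)^2
  (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
}

#' Smirnov-Grubbs outlier screening
#'
#' One-sided (upper) Grubbs test on Procrustes distances from the mean
#' shape: aberrant specimens show up as unusually *large* distances, so only
#' the upper tail is tested. The statistic is
#' \eqn{G = (\max d_i - \bar d)/s_d}. With `iterative = TRUE` the flagged
#' specimen is removed and the test repeated (invoking `refit`, e.g. a
#' re-superimposition of the retained set, to recompute distances) until no
#' outlier remains; the default is a single pass.
#'
#' @param distances named numeric vector of distances to the mean shape
#'   (names are specimen ids).
#' @param alpha significance level.
#' @param iterative repeat removal until no outlier.
#' @param refit optional function(ids_retained) returning new distances for
#'   the retained specimens, called between iterative rounds.
#' @return An `outlier_report`: `tested_n`, `statistic`, `critical_value`,
#'   `alpha`, `outlier_ids` (in removal order), `degenerate_sd` flag.
#' @export
grubbs_screen <- function(distances, alpha = 0.05, iterative = FALSE,
                          refit = NULL) {
  if (length(distances) < 3) stop("Grubbs test needs n >= 3")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  if (is.null(names(distances)))
    names(distances) <- sprintf("spec_%d", seq_along(distances))
  d <- distances
  removed <- character(0)
  first_g <- first_crit <- NA_real_
  degenerate <- FALSE
  repeat {
    s <- stats::sd(d)
    if (!is.finite(s) || s <= .Machine$double.eps * max(abs(d), 1)) {
      degenerate <- TRUE
      if (is.na(first_g)) { first_g <- 0; first_crit <- grubbs_critical(length(d), alpha) }
      break
    }
    g <- (max(d) - mean(d)) / s
    crit <- grubbs_critical(length(d), alpha)
    if (is.na(first_g)) { first_g <- g; first_crit <- crit }
    if (g <= crit) break
    out_id <- names(d)[which.max(d)]
    removed <- c(removed, out_id)
    if (!iterative) break
    keep <- setdiff(names(d), removed)
    if (length(keep) < 3) break
    d <- if (is.null(refit)) d[keep] else {
      nd <- refit(keep)
      if (is.null(names(nd))) names(nd) <- keep
      nd
    }
  }
  structure(list(tested_n = length(distances), statistic = first_g,
                 critical_value = first_crit, alpha = alpha,
                 outlier_ids = removed, degenerate_sd = degenerate),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf(
    "Grubbs screen (alpha = %g): G = %.4f, critical = %.4f, %d outlier(s)%s\n",
    x$alpha, x$statistic, x$critical_value, length(x$outlier_ids),
    if (length(x$outlier_ids))
      paste0(": ", paste(x$outlier_ids, collapse = ", ")) else ""))
  if (x$degenerate_sd) cat("note: zero variance among distances\n")
  invisible(x)
}

#' Write an outlier report as JSON
#'
#' @param report an `outlier_report`.
#' @param path output path.
#' @export
write_outlier_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
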