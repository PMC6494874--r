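#' Egger regression test for funnel-plot asymmetry
#'
#' Classical form: ordinary least squares of the standardised effect
#' `z_i = y_i / sqrt(v_i)` on precision `1/sqrt(v_i)`. A non-zero intercept
#' indicates funnel asymmetry; the test statistic is
#' `z = b0 / SE(b0)` with a two-sided normal p-value. A precision-weighted
#' multilevel variant (effect regressed on its standard error inside a
#' random-effects model) is available via `variant = "multilevel"` for
#' sensitivity analysis.
#'
#' @param yi Effect sizes.
#' @param vi Sampling variances.
#' @param variant `"classical"` (default) or `"multilevel"`.
#' @param random Random levels for the multilevel variant.
#' @param data Data frame with grouping columns (multilevel variant only).
#' @return List of class `egger_test`: `intercept`, `se`, `z`, `p`,
#'   `slope`, `variant`.
#' @export
egger_test <- function(yi, vi, variant = c("classical", "multilevel"),
                       random = c("study", "trait", "taxon"), data = NULL) {
  variant <- match.arg(variant)
  if (length(yi) < 3) stop("need at least three effects", call. = FALSE)
  if (any(vi <= 0)) stop("all sampling variances must be > 0", call. = FALSE)
  prec <- 1 / sqrt(vi)
  if (stats::sd(prec) == 0)
    stop("constant precision across records: asymmetry undefined", call. = FALSE)
  if (variant == "classical") {
    z_std <- yi / sqrt(vi)
    m <- stats::lm(z_std ~ prec)
    sm <- summary(m)$coefficients
    b0 <- sm[1, 1]; se0 <- sm[1, 2]
    out <- list(intercept = b0, se = se0, z = b0 / se0,
                p = 2 * stats::pnorm(-abs(b0 / se0)),
                slope = sm[2, 1], variant = variant)
  } else {
    # sqrt(vi) as a moderator inside the multilevel model
    if (is.null(data)) data <- data.frame(row.names = seq_along(yi))
    data$sei_ <- sqrt(vi)
    fit <- reml_mv(yi, vi, mods = ~ sei_, random = random, data = data)
    out <- list(intercept = fit$beta[["sei_"]], se = fit$se[["sei_"]],
                z = fit$zval[["sei_"]], p = fit$pval[["sei_"]],
                slope = fit$beta[[1]], variant = variant)
  }
  class(out) <- "egger_test"
  out
}

#' @export
print.egger_test <- function(x, ...) {
  cat(sprintf("Egger test (%s): intercept %.4f (SE %.4f), z = %.3f, p = %.4g\n",
              x$variant, x$intercept, x$se, x$z, x$p))
  invisible(x)
}

#' Trend regression of effect size on a covariate
#'
#' Unweighted least-squares regression of effect size on publication year
#' or journal impact factor; rows with a missing covariate are dropped
#' (df = number of usable records minus 2). A precision-weighted option
#' (`weights = 1/vi`) is available.
#'
#' @param yi Effect sizes.
#' @param x Covariate (year or impact factor); may contain `NA`.
#' @param weights Optional regression weights.
#' @return List of class `trend_regression`: `slope`, `se`, `t`, `df`,
#'   `p`, `n_used`.
#' @export
trend_regression <- function(yi, x, weights = NULL) {
  keep <- is.finite(yi) & is.finite(x)
  if (sum(keep) < 3) stop("need at least three records with the covariate",
                          call. = FALSE)
  yi <- yi[keep]; x <- x[keep]
  if (stats::sd(x) == 0) stop("constant covariate: trend undefined", call. = FALSE)
  w <- if (is.null(weights)) NULL else weights[keep]
  m <- if (is.null(w)) stats::lm(yi ~ x) else stats::lm(yi ~ x, weights = w)
  sm <- summary(m)$coefficients
  df <- m$df.residual
  structure(list(slope = sm[2, 1], se = sm[2, 2], t = sm[2, 3], df = df,
                 p = sm[2, 4], n_used = sum(keep), model = m),
            class = "trend_regression")
}

#' @export
print.trend_regression <- function(x, ...) {
  cat(sprintf("trend: slope %.5f (SE %.5f), t_%d = %.3f, p = %.4g (n = %d)\n",
              x$slope, x$se, x$df, x$t, x$p, x$n_used))
  invisible(x)
}

#' Funnel-plot export table
#'
#' Plot-ready data for a funnel plot: each effect with its standard error,
#' the pooled mean, and pseudo-confidence envelopes. At standard error `s`
#' the envelope half-width is `z_alpha * s` (1.96 for 95%, 3.09 for
#' 99.8%), collapsing to the pooled mean at `s = 0`.
#'
#' @param yi Effect sizes.
#' @param vi Sampling variances.
#' @param pooled Pooled mean for the centre line; defaults to the
#'   inverse-variance weighted mean.
#' @param n_grid Number of SE grid points for the envelope table.
#' @return List with `points` (data.frame `yi`, `se`), `pooled`, and
#'   `envelope` (data.frame `se`, `lo95`, `hi95`, `lo998`, `hi998`).
#' @export
funnel_table <- function(yi, vi, pooled = NULL, n_grid = 50) {
  se <- sqrt(vi)
  if (is.null(pooled)) pooled <- sum(yi / vi) / sum(1 / vi)
  grid <- seq(0, max(se), length.out = n_grid)
  z95 <- stats::qnorm(0.975)
  z998 <- stats::qnorm(0.999)
  list(points = data.frame(yi = yi, se = se),
       pooled = pooled,
       envelope = data.frame(se = grid,
                             lo95 = pooled - z95 * grid,
                             hi95 = pooled + z95 * grid,
                             lo998 = pooled - z998 * grid,
                             hi998 = pooled + z998 * grid))
}
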