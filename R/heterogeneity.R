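#' Typical sampling variance
#'
#' The "typical" within-study sampling variance used in the multilevel I2
#' formulation:
#' \deqn{\bar v = \frac{(k-1)\sum w_i}{(\sum w_i)^2 - \sum w_i^2}, \quad
#'       w_i = 1/v_i.}
#' When all variances are equal it reduces to that common value.
#'
#' @param vi Sampling variances (all > 0, at least two).
#' @return The typical sampling variance, a positive scalar.
#' @export
typical_v <- function(vi) {
  if (length(vi) < 2) stop("need at least two sampling variances", call. = FALSE)
  if (any(!is.finite(vi) | vi <= 0))
    stop("all sampling variances must be positive", call. = FALSE)
  w <- 1 / vi
  (length(vi) - 1) * sum(w) / (sum(w)^2 - sum(w^2))
}

#' Multilevel I2 heterogeneity partition
#'
#' Expresses each variance component as a percentage of the total variance
#' (true heterogeneity plus typical sampling variance):
#' \deqn{I^2_l = 100\,\hat\sigma^2_l / (\textstyle\sum_m \hat\sigma^2_m + \bar v)}
#' so the per-level values sum exactly to the total
#' \eqn{I^2 = 100 \sum_l \hat\sigma^2_l / (\sum_m \hat\sigma^2_m + \bar v)}.
#' Optional confidence intervals by parametric bootstrap: new effect
#' vectors are simulated from the fitted model (fixed effects plus normal
#' level deviations and sampling noise), refitted, and percentile intervals
#' taken over the replicate I2 values.
#'
#' @param fit A converged [reml_mv()] fit.
#' @param B Number of parametric-bootstrap replicates for CIs (0 = none).
#' @param seed Seed for the bootstrap.
#' @param level CI level (default 0.95).
#' @return Object of class `heterogeneity_result`: `typical_v`, `i2_total`,
#'   `i2_per_level` (named, percent), and with `B > 0` a `ci95` matrix and
#'   `method_ci` label.
#' @export
i2_partition <- function(fit, B = 0, seed = NULL, level = 0.95) {
  stopifnot(inherits(fit, "reml_fit"))
  if (!fit$converged) warning("fit did not converge; I2 partition may be unreliable")
  vbar <- typical_v(fit$vi)
  s2 <- fit$sigma2
  denom <- sum(s2) + vbar
  per <- 100 * s2 / denom
  out <- list(typical_v = vbar,
              i2_total = 100 * sum(s2) / denom,
              i2_per_level = per,
              ci95 = NULL, method_ci = "none")
  if (B > 0) {
    if (!is.null(seed)) set.seed(seed)
    mu <- drop(fit$X %*% fit$beta)
    k <- fit$k
    reps <- matrix(NA_real_, B, length(s2) + 1)
    for (b in seq_len(B)) {
      y <- mu + stats::rnorm(k, 0, sqrt(fit$vi))
      for (l in seq_along(fit$Z)) {
        Zl <- fit$Z[[l]]
        y <- y + drop(Zl %*% stats::rnorm(ncol(Zl), 0, sqrt(s2[l])))
      }
      fb <- tryCatch(
        reml_mv(y, fit$vi, mods = fit$mods, random = fit$random,
                data = fit$data, control = list(nstarts = 1)),
        error = function(e) NULL)
      if (is.null(fb)) next
      vb <- typical_v(fb$vi)
      db <- sum(fb$sigma2) + vb
      reps[b, ] <- c(100 * sum(fb$sigma2) / db, 100 * fb$sigma2 / db)
    }
    a <- (1 - level) / 2
    ci <- t(apply(reps, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE))
    rownames(ci) <- c("total", names(s2))
    out$ci95 <- ci
    out$method_ci <- sprintf("parametric bootstrap (B = %d)", B)
  }
  class(out) <- "heterogeneity_result"
  out
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Typical sampling variance: %.5f\n", x$typical_v))
  cat(sprintf("I2 total: %.1f%%\n", x$i2_total))
  for (nm in names(x$i2_per_level)) {
    cat(sprintf("  I2 %s: %.1f%%\n", nm, x$i2_per_level[[nm]]))
  }
  if (!is.null(x$ci95)) {
    cat("95% CIs (", x$method_ci, "):\n", sep = "")
    print(round(x$ci95, 1))
  }
  invisible(x)
}
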