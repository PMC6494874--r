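#' @name effect-sizes
#' @title Effect-size measures with sampling variances
#'
#' @description
#' Converters from two-group summaries or test statistics to the four
#' effect-size measures used by the pipeline:
#'
#' * `hedges_g()` — small-sample-corrected standardised mean difference
#'   (Hedges' g) from group means, SDs and sample sizes;
#' * `g_from_t()`, `g_from_f()`, `g_from_chisq()`, `g_from_proportions()` —
#'   Hedges' g reconstructed from a t, F or 1-df chi-square statistic, or
#'   from a difference in proportions;
#' * `lnrr()` — log response ratio of means;
#' * `lncvr()` — log ratio of coefficients of variation (relative
#'   variability, controlling for the mean--variance relationship);
#' * `lnvr()` — bias-corrected log ratio of standard deviations (absolute
#'   variability).
#'
#' All converters return a list of class `effect_size` with elements
#' `measure`, `value`, `variance` and (for the g family) `detail` holding
#' the uncorrected standardised difference `d`, the small-sample correction
#' `J = 1 - 3/(4 df - 1)` and `df`.
NULL

.es <- function(measure, value, variance, detail = NULL) {
  stopifnot(is.finite(value), is.finite(variance), variance > 0)
  structure(list(measure = measure, value = value, variance = variance,
                 detail = detail), class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("%s = %.4f (sampling variance %.5f, SE %.4f)\n",
              x$measure, x$value, x$variance, sqrt(x$variance)))
  invisible(x)
}

# g-family finisher: apply Hedges' small-sample correction to d and compute
# the J^2-scaled sampling variance of g
.g_finish <- function(d, n_high, n_low) {
  n_high <- as.numeric(n_high)  # avoid integer overflow in n_h * n_l
  n_low <- as.numeric(n_low)
  df <- n_high + n_low - 2
  J <- 1 - 3 / (4 * df - 1)
  var_d <- (n_high + n_low) / (n_high * n_low) + d^2 / (2 * (n_high + n_low))
  .es("g", J * d, J^2 * var_d,
      detail = list(d = d, J = J, df = df))
}

.check_n <- function(n_high, n_low) {
  if (!is.finite(n_high) || !is.finite(n_low) || n_high < 2 || n_low < 2)
    stop("both group sample sizes must be >= 2", call. = FALSE)
}

#' Hedges' g from two-group summaries
#'
#' Computes the standardised mean difference
#' `d = (m_high - m_low) / s_pooled` with the pooled SD
#' `s_pooled = sqrt(((n_h - 1) s_h^2 + (n_l - 1) s_l^2) / (n_h + n_l - 2))`,
#' then applies the small-sample correction `J = 1 - 3/(4 df - 1)` with
#' `df = n_h + n_l - 2`: `g = J d`, sampling variance
#' `J^2 ((n_h + n_l)/(n_h n_l) + d^2 / (2 (n_h + n_l)))`.
#'
#' @param m_high,s_high,n_high Mean, SD and sample size of the
#'   high-sexual-selection group.
#' @param m_low,s_low,n_low Mean, SD and sample size of the low group.
#' @return An `effect_size` (measure `"g"`).
#' @export
hedges_g <- function(m_high, s_high, n_high, m_low, s_low, n_low) {
  .check_n(n_high, n_low)
  if (s_high < 0 || s_low < 0) stop("SDs must be non-negative", call. = FALSE)
  sp2 <- ((n_high - 1) * s_high^2 + (n_low - 1) * s_low^2) /
    (n_high + n_low - 2)
  if (sp2 <= 0) stop("pooled SD is zero: standardised difference undefined",
                     call. = FALSE)
  .g_finish((m_high - m_low) / sqrt(sp2), n_high, n_low)
}

#' Hedges' g from a t statistic
#'
#' `d = t sqrt((n_h + n_l) / (n_h n_l))`; the sign of `t` carries the
#' direction of the difference (high minus low).
#'
#' @param t Two-sample t statistic.
#' @param n_high,n_low Group sample sizes.
#' @return An `effect_size` (measure `"g"`).
#' @export
g_from_t <- function(t, n_high, n_low) {
  .check_n(n_high, n_low)
  n_high <- as.numeric(n_high)
  n_low <- as.numeric(n_low)
  .g_finish(t * sqrt((n_high + n_low) / (n_high * n_low)), n_high, n_low)
}

#' Hedges' g from a one-way F statistic
#'
#' For a two-group comparison `F = t^2`, so
#' `d = sqrt(F (n_h + n_l) / (n_h n_l))`; the F statistic is unsigned and
#' the direction of the difference must be supplied.
#'
#' @param f F statistic (numerator df must be 1).
#' @param n_high,n_low Group sample sizes.
#' @param direction `+1` if the high-sexual-selection group scored higher,
#'   `-1` otherwise.
#' @param df1 Numerator degrees of freedom; values other than 1 are
#'   rejected because the mapping to a two-group difference is not unique.
#' @return An `effect_size` (measure `"g"`).
#' @export
g_from_f <- function(f, n_high, n_low, direction = 1, df1 = 1) {
  .check_n(n_high, n_low)
  if (df1 != 1) stop("F statistics with numerator df > 1 are not supported",
                     call. = FALSE)
  if (f < 0) stop("F must be non-negative", call. = FALSE)
  n_high <- as.numeric(n_high)
  n_low <- as.numeric(n_low)
  d <- sign(direction) * sqrt(f * (n_high + n_low) / (n_high * n_low))
  .g_finish(d, n_high, n_low)
}

#' Hedges' g from a 1-df chi-square statistic
#'
#' Converts through the phi coefficient: `r = sqrt(chisq / N)`,
#' `d = 2 r / sqrt(1 - r^2)`, signed by `direction`.
#'
#' @param chisq Chi-square statistic from a 1-df test.
#' @param n_high,n_low Group sample sizes (their sum is the total N of the
#'   test).
#' @param direction `+1`/`-1` direction of the reported difference.
#' @param df Degrees of freedom of the chi-square test; only 1 is
#'   supported.
#' @return An `effect_size` (measure `"g"`).
#' @export
g_from_chisq <- function(chisq, n_high, n_low, direction = 1, df = 1) {
  .check_n(n_high, n_low)
  if (df != 1) stop("chi-square statistics with df > 1 are not supported",
                    call. = FALSE)
  if (chisq < 0) stop("chi-square must be non-negative", call. = FALSE)
  N <- n_high + n_low
  r <- sqrt(chisq / N)
  if (r >= 1) stop("chi-square implies |r| >= 1: conversion undefined",
                   call. = FALSE)
  d <- sign(direction) * 2 * r / sqrt(1 - r^2)
  .g_finish(d, n_high, n_low)
}

#' Hedges' g from a difference in proportions
#'
#' Uses the Cox logit transform:
#' `d = (logit(p_high) - logit(p_low)) / 1.65`. Degenerate proportions
#' (exactly 0 or 1) are handled by a continuity rule on the underlying
#' count: for `p = x/n = 1` the numerator is reduced by one (`(x-1)/n`)
#' before the logit; for `p = 0` it is raised by one (`1/n`). The rule
#' needs the group count, so degenerate proportions with unknown counts are
#' an error.
#'
#' @param p_high,p_low Group proportions in \[0, 1\].
#' @param n_high,n_low Group sample sizes.
#' @return An `effect_size` (measure `"g"`).
#' @export
g_from_proportions <- function(p_high, p_low, n_high, n_low) {
  .check_n(n_high, n_low)
  fix <- function(p, n) {
    if (is.na(p) || p < 0 || p > 1)
      stop("proportions must lie in [0, 1]", call. = FALSE)
    if (p == 1) {
      if (!is.finite(n)) stop("proportion of 1 with unknown count", call. = FALSE)
      p <- (n - 1) / n
    } else if (p == 0) {
      if (!is.finite(n)) stop("proportion of 0 with unknown count", call. = FALSE)
      p <- 1 / n
    }
    p
  }
  ph <- fix(p_high, n_high)
  pl <- fix(p_low, n_low)
  logit <- function(p) log(p / (1 - p))
  d <- (logit(ph) - logit(pl)) / 1.65
  .g_finish(d, n_high, n_low)
}

#' Log response ratio (lnRR)
#'
#' `lnRR = ln(m_high / m_low)` with sampling variance
#' `s_h^2/(n_h m_h^2) + s_l^2/(n_l m_l^2)`. Requires strictly positive
#' means.
#'
#' @inheritParams hedges_g
#' @return An `effect_size` (measure `"lnRR"`).
#' @export
lnrr <- function(m_high, s_high, n_high, m_low, s_low, n_low) {
  .check_n(n_high, n_low)
  if (m_high <= 0 || m_low <= 0)
    stop("lnRR requires strictly positive means", call. = FALSE)
  .es("lnRR", log(m_high / m_low),
      s_high^2 / (n_high * m_high^2) + s_low^2 / (n_low * m_low^2))
}

#' Log coefficient of variation ratio (lnCVR)
#'
#' `lnCVR = ln((s_high/m_high) / (s_low/m_low))` — the relative-variability
#' contrast that implicitly controls for the mean--variance relationship.
#' The sampling variance allows a mean--SD correlation `rho` within groups;
#' with the default `rho = 0` it reduces to
#' `s_h^2/(n_h m_h^2) + 1/(2(n_h-1)) + s_l^2/(n_l m_l^2) + 1/(2(n_l-1))`.
#'
#' @inheritParams hedges_g
#' @param rho Correlation between log mean and log SD within a group, in
#'   \[-1, 1\].
#' @return An `effect_size` (measure `"lnCVR"`).
#' @export
lncvr <- function(m_high, s_high, n_high, m_low, s_low, n_low, rho = 0) {
  .check_n(n_high, n_low)
  if (s_high <= 0 || s_low <= 0)
    stop("lnCVR requires strictly positive SDs", call. = FALSE)
  if (m_high <= 0 || m_low <= 0)
    stop("lnCVR requires strictly positive means", call. = FALSE)
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]", call. = FALSE)
  vm_h <- s_high^2 / (n_high * m_high^2)  # var of log mean, high group
  vs_h <- 1 / (2 * (n_high - 1))          # var of log SD, high group
  vm_l <- s_low^2 / (n_low * m_low^2)
  vs_l <- 1 / (2 * (n_low - 1))
  v <- vm_h + vs_h + vm_l + vs_l -
    2 * rho * (sqrt(vm_h) * sqrt(vs_h) + sqrt(vm_l) * sqrt(vs_l))
  .es("lnCVR", log((s_high / m_high) / (s_low / m_low)), v)
}

#' Log variability ratio (lnVR)
#'
#' Bias-corrected log ratio of SDs:
#' `lnVR = ln(s_high/s_low) + 1/(2(n_h-1)) - 1/(2(n_l-1))`, sampling
#' variance `1/(2(n_h-1)) + 1/(2(n_l-1))`. Absolute variability contrast,
#' irrespective of the means.
#'
#' @inheritParams hedges_g
#' @return An `effect_size` (measure `"lnVR"`).
#' @export
lnvr <- function(s_high, n_high, s_low, n_low) {
  .check_n(n_high, n_low)
  if (s_high <= 0 || s_low <= 0)
    stop("lnVR requires strictly positive SDs", call. = FALSE)
  .es("lnVR",
      log(s_high / s_low) + 1 / (2 * (n_high - 1)) - 1 / (2 * (n_low - 1)),
      1 / (2 * (n_high - 1)) + 1 / (2 * (n_low - 1)))
}

#' Compute effect sizes for a whole table of records
#'
#' Applies the appropriate converter to every record: for measure `"g"`,
#' records are dispatched on `input_kind` (summaries, t, F, chisq,
#' proportions); the ratio measures (`"lnRR"`, `"lnCVR"`, `"lnVR"`) require
#' two-group summaries and records without them (or violating positivity
#' preconditions) are skipped with a log entry. Raw effects are then
#' sign-oriented with [orient_sign()] so that positive values always mean
#' higher fitness under sexual selection.
#'
#' @param data Data frame of effect records (canonical schema).
#' @param measure One of `"g"`, `"lnRR"`, `"lnCVR"`, `"lnVR"`.
#' @param rho Mean--SD correlation passed to [lncvr()].
#' @param quiet Suppress the skipped-record message.
#' @return The input rows for which the measure is computable, with columns
#'   `yi` (oriented effect), `vi` (sampling variance) and `measure`
#'   appended. Attributes `n_skipped` and `skip_reasons` record the rows
#'   that could not be converted.
#' @export
compute_effect_sizes <- function(data, measure = c("g", "lnRR", "lnCVR", "lnVR"),
                                 rho = 0, quiet = FALSE) {
  measure <- match.arg(measure)
  n <- nrow(data)
  yi <- vi <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  has_summ <- !is.na(data$input_kind) & data$input_kind == "summaries" &
    !is.na(data$m_high) & !is.na(data$s_high) & !is.na(data$n_high) &
    !is.na(data$m_low) & !is.na(data$s_low) & !is.na(data$n_low)
  for (i in seq_len(n)) {
    es <- tryCatch({
      if (measure == "g") {
        kind <- data$input_kind[i]
        dir <- if (is.na(data$direction[i])) 1 else data$direction[i]
        nh <- data$n_high[i]; nl <- data$n_low[i]
        if (is.na(kind)) stop("input_kind missing")
        switch(kind,
          summaries = hedges_g(data$m_high[i], data$s_high[i], nh,
                               data$m_low[i], data$s_low[i], nl),
          t = g_from_t(dir * abs(data$statistic_value[i]), nh, nl),
          "F" = g_from_f(data$statistic_value[i], nh, nl, direction = dir),
          chisq = g_from_chisq(data$statistic_value[i], nh, nl, direction = dir),
          proportions = g_from_proportions(data$m_high[i], data$m_low[i], nh, nl),
          stop("unknown input_kind")
        )
      } else {
        if (!has_summ[i]) stop("group summaries unavailable")
        switch(measure,
          lnRR = lnrr(data$m_high[i], data$s_high[i], data$n_high[i],
                      data$m_low[i], data$s_low[i], data$n_low[i]),
          lnCVR = lncvr(data$m_high[i], data$s_high[i], data$n_high[i],
                        data$m_low[i], data$s_low[i], data$n_low[i], rho = rho),
          lnVR = lnvr(data$s_high[i], data$n_high[i],
                      data$s_low[i], data$n_low[i])
        )
      }
    }, error = function(e) e)
    if (inherits(es, "error")) {
      reason[i] <- conditionMessage(es)
    } else {
      yi[i] <- es$value
      vi[i] <- es$variance
    }
  }
  keep <- !is.na(yi)
  out <- data[keep, , drop = FALSE]
  neg <- if ("negatively_related" %in% names(data)) {
    data$negatively_related[keep]
  } else {
    trait_is_negative(data$trait[keep])
  }
  out$yi <- orient_sign(yi[keep], neg)
  out$vi <- vi[keep]
  out$measure <- rep(measure, nrow(out))
  rownames(out) <- NULL
  n_skipped <- sum(!keep)
  if (n_skipped && !quiet) {
    message(sprintf("%s: %d of %d record(s) skipped (%s)", measure,
                    n_skipped, n,
                    paste(utils::head(unique(reason[!keep]), 3), collapse = "; ")))
  }
  attr(out, "n_skipped") <- n_skipped
  attr(out, "skip_reasons") <- reason[!keep]
  out
}
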