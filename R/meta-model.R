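#' Build fixed- and random-effect design matrices
#'
#' Constructs the moderator design matrix with treatment coding (reference
#' levels `male` for sex and `benign` for environment, so that the
#' intercept is the male/benign cell) and one indicator matrix per random
#' level mapping effects to their groups.
#'
#' @param data Data frame of effect records with computed `yi`/`vi`.
#' @param mods Moderator formula, e.g. `~ 1`, `~ fitness_class` or
#'   `~ sex * environment`.
#' @param random Character vector of random levels: any of `"study"`,
#'   `"trait"`, `"taxon"`, `"effect"` (`"effect"` is the observation-level
#'   residual heterogeneity term).
#' @return List with `X` (fixed design), `Z` (named list of indicator
#'   matrices) and `xlev` (factor levels used).
#' @export
build_design <- function(data, mods = ~ 1,
                         random = c("study", "trait", "taxon")) {
  stopifnot(length(random) >= 1)
  df <- data
  # reference levels: male sex, benign environment
  if ("sex" %in% names(df)) {
    df$sex <- factor(df$sex, levels = c("male", "female", "both"))
  }
  if ("environment" %in% names(df)) {
    df$environment <- factor(df$environment,
                             levels = c("benign", "stressful", "undefined"))
    df$environment <- droplevels(df$environment)
  }
  vars <- all.vars(mods)
  for (v in vars) {
    if (!v %in% names(df)) stop("unknown moderator: ", v, call. = FALSE)
    if (!is.factor(df[[v]]) && !is.numeric(df[[v]])) df[[v]] <- factor(df[[v]])
    if (is.factor(df[[v]])) {
      df[[v]] <- droplevels(df[[v]])
      if (anyNA(df[[v]]))
        stop("missing values in moderator '", v, "'", call. = FALSE)
    }
  }
  mf <- stats::model.frame(mods, df)
  X <- stats::model.matrix(mods, mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient moderator design; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  col_map <- c(study = "study_id", trait = "trait", taxon = "taxon")
  Z <- list()
  for (lv in random) {
    if (lv == "effect") {
      Z[[lv]] <- diag(nrow(df))
    } else {
      cn <- col_map[[lv]]
      if (is.null(cn) || !cn %in% names(df))
        stop("unknown random level: ", lv, call. = FALSE)
      f <- factor(df[[cn]])
      Z[[lv]] <- stats::model.matrix(~ 0 + f)
    }
  }
  list(X = X, Z = Z,
       xlev = lapply(Filter(is.factor, df[vars]), levels),
       terms = stats::terms(mods))
}

# restricted log-likelihood (up to an additive constant) and GLS pieces for
# V = diag(vi) + sum_l sigma2_l Z_l Z_l'
.reml_pieces <- function(sigma2, vi, X, ZZt) {
  k <- length(vi)
  V <- diag(vi, k)
  for (l in seq_along(ZZt)) V <- V + sigma2[l] * ZZt[[l]]
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) return(NULL)
  W <- backsolve(L, cbind(X, yi = attr(ZZt, "yi")), transpose = TRUE)
  p <- ncol(X)
  Xt <- W[, seq_len(p), drop = FALSE]
  yt <- W[, p + 1]
  XtViX <- crossprod(Xt)
  cXtViX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cXtViX)) return(NULL)
  beta <- backsolve(cXtViX, backsolve(cXtViX, crossprod(Xt, yt),
                                      transpose = TRUE))
  r <- yt - Xt %*% beta
  ll <- -0.5 * (2 * sum(log(diag(L))) + 2 * sum(log(diag(cXtViX))) +
                  sum(r^2))
  list(ll = ll, beta = drop(beta), vb = chol2inv(cXtViX))
}

.reml_obj <- function(theta, vi, X, ZZt) {
  pc <- .reml_pieces(exp(theta), vi, X, ZZt)
  if (is.null(pc) || !is.finite(pc$ll)) return(1e10)
  -pc$ll
}

#' Fit a multilevel random-effects meta-regression by REML
#'
#' Estimates the variance component of each random level by maximising the
#' restricted log-likelihood
#' \deqn{-\tfrac12\left[\ln|V| + \ln|X^\top V^{-1}X| +
#'       (y - X\hat\beta)^\top V^{-1}(y - X\hat\beta)\right]}
#' with \eqn{V = \mathrm{diag}(v) + \sum_l \sigma^2_l Z_l Z_l^\top} and the
#' GLS solution \eqn{\hat\beta = (X^\top V^{-1}X)^{-1}X^\top V^{-1}y}.
#' Optimisation is over \eqn{\log\sigma^2_l} (floor `1e-10`) by
#' quasi-Newton iteration with restarts from 0.001 and from 0.1 and 1 times
#' a method-of-moments estimate; components converging to the floor are
#' reported as exactly 0. Wald inference: `z = beta/SE` with two-sided
#' normal p-values and 95% CIs at `beta +/- 1.96 SE`.
#'
#' @param yi Effect sizes (or a data frame holding `yi`/`vi`, in which case
#'   `vi` may be omitted).
#' @param vi Sampling variances (all > 0).
#' @param mods Moderator formula (default intercept only).
#' @param random Random levels, see [build_design()].
#' @param data Data frame with moderator and grouping columns; defaults to
#'   `yi` when that is a data frame.
#' @param sigma2 Optional fixed variance components (one per random level);
#'   when supplied no optimisation is done — `sigma2 = 0` for all levels
#'   reproduces fixed-effect inverse-variance weighted least squares
#'   exactly.
#' @param control List: `nstarts` (1--3, default 3), `rel.tol` objective
#'   tolerance (default 1e-12), `verbose`.
#' @return Object of class `reml_fit`: `beta`, `se`, `zval`, `pval`,
#'   `ci.lb`, `ci.ub`, `vb` (covariance of beta), `sigma2` (named),
#'   `loglik`, `k`, `p`, `converged`, plus the design pieces needed for
#'   contrasts, predictions and the heterogeneity partition.
#' @export
reml_mv <- function(yi, vi = NULL, mods = ~ 1,
                    random = c("study", "trait", "taxon"),
                    data = NULL, sigma2 = NULL,
                    control = list()) {
  if (is.data.frame(yi)) {
    data <- yi
    vi <- data$vi
    yi <- data$yi
  }
  if (is.null(data)) data <- data.frame(row.names = seq_along(yi))
  stopifnot(length(yi) == length(vi), all(is.finite(yi)), all(is.finite(vi)))
  if (any(vi <= 0)) stop("all sampling variances must be > 0", call. = FALSE)
  des <- build_design(data, mods = mods, random = random)
  X <- des$X
  k <- length(yi)
  p <- ncol(X)
  if (k <= p) stop("need more effects than fixed parameters", call. = FALSE)
  ZZt <- lapply(des$Z, tcrossprod)
  names(ZZt) <- names(des$Z)
  attr(ZZt, "yi") <- yi

  ctl <- utils::modifyList(list(nstarts = 3, rel.tol = 1e-12,
                                verbose = FALSE), control)
  L <- length(ZZt)
  converged <- TRUE
  if (is.null(sigma2)) {
    # method-of-moments style start from the residual Q statistic
    w <- 1 / vi
    bw <- stats::lm.wfit(X, yi, w)$coefficients
    Q <- sum(w * (yi - drop(X %*% bw))^2)
    tau2_mom <- max((Q - (k - p)) / sum(w), 1e-3)
    starts <- list(rep(tau2_mom / L, L),
                   rep(0.1 * tau2_mom / L, L),
                   rep(1e-3, L))[seq_len(max(1, min(3, ctl$nstarts)))]
    best <- NULL
    for (s0 in starts) {
      op <- tryCatch(
        stats::nlminb(log(s0), .reml_obj, vi = vi, X = X, ZZt = ZZt,
                      lower = log(1e-10), upper = log(1e4),
                      control = list(rel.tol = ctl$rel.tol, iter.max = 500,
                                     eval.max = 1000)),
        error = function(e) NULL)
      if (is.null(op)) next
      if (is.null(best) || op$objective < best$objective - 1e-12) best <- op
    }
    if (is.null(best)) stop("REML optimisation failed", call. = FALSE)
    # components on the boundary make nlminb report "singular convergence";
    # accept any solution that a restart from the optimum cannot improve
    polish <- tryCatch(
      stats::nlminb(best$par, .reml_obj, vi = vi, X = X, ZZt = ZZt,
                    lower = log(1e-10), upper = log(1e4),
                    control = list(rel.tol = ctl$rel.tol, iter.max = 500,
                                   eval.max = 1000)),
      error = function(e) NULL)
    if (is.null(polish)) {
      converged <- best$convergence == 0
    } else {
      stationary <- abs(polish$objective - best$objective) < 1e-6 &&
        is.finite(polish$objective)
      if (polish$objective <= best$objective) best <- polish
      converged <- best$convergence == 0 || stationary
    }
    sigma2 <- exp(best$par)
    sigma2[sigma2 <= 1e-8] <- 0  # boundary estimates reported as exact zeros
  } else {
    if (length(sigma2) == 1) sigma2 <- rep(sigma2, L)
    stopifnot(length(sigma2) == L, all(sigma2 >= 0))
  }
  pc <- .reml_pieces(sigma2, vi, X, ZZt)
  if (is.null(pc)) stop("variance matrix not positive definite", call. = FALSE)
  names(sigma2) <- names(ZZt)
  beta <- pc$beta
  names(beta) <- colnames(X)
  se <- sqrt(diag(pc$vb))
  names(se) <- colnames(X)
  zval <- beta / se
  fit <- structure(list(
    beta = beta, se = se, zval = zval,
    pval = 2 * stats::pnorm(-abs(zval)),
    ci.lb = beta - 1.96 * se, ci.ub = beta + 1.96 * se,
    vb = pc$vb, sigma2 = sigma2, loglik = pc$ll,
    k = k, p = p, converged = converged,
    yi = yi, vi = vi, X = X, Z = des$Z,
    mods = mods, random = names(ZZt), xlev = des$xlev,
    data = data
  ), class = "reml_fit")
  if (!converged) warning("REML optimiser did not report convergence; ",
                          "inspect the fit before using it", call. = FALSE)
  fit
}

#' @export
print.reml_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Multilevel meta-regression (REML), k = %d effects\n", x$k))
  cat("Variance components:\n")
  print(round(x$sigma2, digits))
  tab <- data.frame(estimate = x$beta, se = x$se, zval = x$zval,
                    pval = x$pval, ci.lb = x$ci.lb, ci.ub = x$ci.ub)
  cat("Fixed effects:\n")
  print(round(tab, digits))
  if (!x$converged) cat("WARNING: optimiser did not converge\n")
  invisible(x)
}

#' Linear contrast of fixed effects
#'
#' Computes `L'beta` with Wald standard error `sqrt(L' vb L)`, normal z
#' test and 95% CI.
#'
#' @param fit A `reml_fit`, or any list with elements `beta` and `vb`.
#' @param L Contrast weight vector, `length(L) == length(beta)`.
#' @return Object of class `contrast_result` with `L`, `estimate`, `se`,
#'   `z`, `p_two_sided`, `ci95`.
#' @export
contrast <- function(fit, L) {
  beta <- fit$beta
  if (length(L) != length(beta))
    stop("contrast length ", length(L), " != number of coefficients ",
         length(beta), call. = FALSE)
  est <- drop(crossprod(L, beta))
  se <- sqrt(drop(t(L) %*% fit$vb %*% L))
  z <- if (se > 0) est / se else NA_real_
  structure(list(L = L, estimate = est, se = se, z = z,
                 p_two_sided = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)),
                 ci95 = c(est - 1.96 * se, est + 1.96 * se)),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("contrast estimate %.4f (SE %.4f, z %.3f, p %.4g, 95%% CI %.4f to %.4f)\n",
              x$estimate, x$se, x$z, x$p_two_sided, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Per-level model predictions
#'
#' Predicted mean effects for every moderator combination present in the
#' fitted data (e.g. one prediction per fitness class, or per sex-by-
#' environment cell), as linear combinations of the fixed effects with
#' Wald 95% CIs.
#'
#' @param fit A `reml_fit`.
#' @param newdata Optional data frame of moderator values to predict at;
#'   defaults to the unique combinations observed in the fitted data.
#' @return Data frame with the moderator columns, `estimate`, `se`,
#'   `ci.lb`, `ci.ub`.
#' @export
predict_levels <- function(fit, newdata = NULL) {
  vars <- all.vars(fit$mods)
  if (!length(vars)) {
    est <- fit$beta[1]; se <- fit$se[1]
    return(data.frame(estimate = est, se = se,
                      ci.lb = est - 1.96 * se, ci.ub = est + 1.96 * se,
                      row.names = NULL))
  }
  if (is.null(newdata)) {
    newdata <- unique(fit$data[vars])
    newdata <- newdata[do.call(order, newdata), , drop = FALSE]
  }
  for (v in vars) {
    if (v %in% names(fit$xlev)) {
      bad <- !newdata[[v]] %in% fit$xlev[[v]]
      if (any(bad)) stop("unknown level(s) for '", v, "': ",
                         paste(unique(newdata[[v]][bad]), collapse = ", "),
                         call. = FALSE)
      newdata[[v]] <- factor(newdata[[v]], levels = fit$xlev[[v]])
    }
  }
  Xn <- stats::model.matrix(fit$mods, stats::model.frame(fit$mods, newdata))
  est <- drop(Xn %*% fit$beta)
  se <- sqrt(rowSums((Xn %*% fit$vb) * Xn))
  out <- data.frame(newdata, estimate = est, se = se,
                    ci.lb = est - 1.96 * se, ci.ub = est + 1.96 * se,
                    row.names = NULL)
  out
}

#' Separate intercept-only meta-analyses per fitness component
#'
#' Splits the dataset by trait and fits an intercept-only REML model with
#' study and taxon as random levels to each trait having more than
#' `min_k - 1` effect sizes; traits at or below the threshold are listed as
#' skipped.
#'
#' @param data Data frame with `yi`, `vi`, `trait`, `study_id`, `taxon`.
#' @param min_k Minimum number of effects required to fit (default 4, i.e.
#'   traits with more than three effects).
#' @param random Random levels for each per-trait fit.
#' @param control Passed to [reml_mv()].
#' @return List with `fits` (named list of `reml_fit`), `skipped`
#'   (character vector of trait labels) and `table` (one row per fitted
#'   trait: k, estimate, se, CI).
#' @export
per_trait_models <- function(data, min_k = 4, random = c("study", "taxon"),
                             control = list()) {
  stopifnot(all(c("yi", "vi", "trait") %in% names(data)))
  traits <- sort(unique(data$trait))
  fits <- list()
  skipped <- character()
  for (tr in traits) {
    sub <- data[data$trait == tr, , drop = FALSE]
    if (nrow(sub) < min_k) {
      skipped <- c(skipped, tr)
      next
    }
    fits[[tr]] <- reml_mv(sub, random = random, control = control)
  }
  tab <- do.call(rbind, lapply(names(fits), function(tr) {
    f <- fits[[tr]]
    data.frame(trait = tr, k = f$k, estimate = f$beta[1], se = f$se[1],
               ci.lb = f$ci.lb[1], ci.ub = f$ci.ub[1], row.names = NULL)
  }))
  list(fits = fits, skipped = skipped, table = tab)
}
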