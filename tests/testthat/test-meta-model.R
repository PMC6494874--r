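test_that("balanced single-level case matches the closed form", {
  # equal sampling variances v, one observation-level component:
  # sigma2_hat = max(0, SS/(k-1) - v), beta_hat = mean, both exact
  y <- c(-2, -1, 0, 1, 2)
  f <- reml_mv(y, rep(1, 5), random = "effect",
               data = data.frame(id = 1:5))
  expect_equal(unname(f$sigma2), 1.5, tolerance = 1e-6)
  expect_equal(unname(f$beta), 0, tolerance = 1e-6)
  expect_equal(unname(f$se), sqrt(2.5 / 5), tolerance = 1e-6)
  expect_true(f$converged)

  # second balanced instance with a non-zero mean
  y2 <- c(1, 2, 3, 4, 5) / 2
  f2 <- reml_mv(y2, rep(0.25, 5), random = "effect",
                data = data.frame(id = 1:5))
  expect_equal(unname(f2$sigma2), max(0, stats::var(y2) - 0.25),
               tolerance = 1e-6)
  expect_equal(unname(f2$beta), mean(y2), tolerance = 1e-6)
})

test_that("identical effects give beta = c and zero heterogeneity", {
  f <- reml_mv(rep(0.4, 6), rep(0.2, 6), random = "effect",
               data = data.frame(id = 1:6))
  expect_equal(unname(f$beta), 0.4)
  expect_equal(unname(f$sigma2), 0)
})

test_that("fixing all components at zero reproduces inverse-variance WLS", {
  set.seed(14)
  k <- 30
  d <- data.frame(study_id = paste0("s", rep(1:10, 3)),
                  x = stats::rnorm(k))
  yi <- 0.3 + 0.5 * d$x + stats::rnorm(k, 0, 0.3)
  vi <- stats::runif(k, 0.05, 0.4)
  f <- reml_mv(yi, vi, mods = ~ x, random = "study", data = d, sigma2 = 0)
  w <- stats::lm(yi ~ d$x, weights = 1 / vi)
  expect_equal(unname(f$beta), unname(stats::coef(w)), tolerance = 1e-10)
  X <- cbind(1, d$x)
  expect_equal(unname(f$vb), solve(t(X) %*% (X / vi)), tolerance = 1e-10)
})

test_that("no grid point near the optimum beats the REML objective", {
  set.seed(7)
  for (rep in 1:3) {
    k <- 25
    d <- data.frame(study_id = paste0("s", sample(1:8, k, replace = TRUE)))
    vi <- stats::runif(k, 0.02, 0.3)
    yi <- toy_meta_sample(k, 0.2, 0.1, vi)
    f <- reml_mv(yi, vi, random = "study", data = d)
    des <- build_design(d, ~1, "study")
    ZZt <- list(study = tcrossprod(des$Z$study))
    attr(ZZt, "yi") <- yi
    obj_hat <- sexselmeta:::.reml_obj(log(pmax(f$sigma2, 1e-10)),
                                      vi, des$X, ZZt)
    grid <- seq(max(f$sigma2 - 0.1, 1e-6), f$sigma2 + 0.1, length.out = 20)
    objs <- sapply(grid, function(s2)
      sexselmeta:::.reml_obj(log(s2), vi, des$X, ZZt))
    expect_true(all(objs >= obj_hat - 1e-7))
  }
})

test_that("estimates are invariant to row permutation and label renaming", {
  set.seed(33)
  k <- 40
  d <- data.frame(study_id = paste0("s", sample(1:12, k, replace = TRUE)),
                  trait = sample(letters[1:5], k, replace = TRUE))
  vi <- stats::runif(k, 0.02, 0.2)
  yi <- toy_meta_sample(k, 0.1, 0.08, vi)
  f1 <- reml_mv(yi, vi, random = c("study", "trait"), data = d)
  perm <- sample(k)
  f2 <- reml_mv(yi[perm], vi[perm], random = c("study", "trait"),
                data = d[perm, , drop = FALSE])
  expect_equal(f1$beta, f2$beta, tolerance = 1e-6)
  expect_equal(f1$sigma2, f2$sigma2, tolerance = 1e-6)
  d3 <- d
  d3$study_id <- paste0("XX_", d3$study_id)
  f3 <- reml_mv(yi, vi, random = c("study", "trait"), data = d3)
  expect_equal(f1$sigma2, f3$sigma2, tolerance = 1e-8)
})

test_that("multilevel fits agree with metafor::rma.mv", {
  skip_if_not_installed("metafor")
  cfg <- sim_config(n_studies = 40, effects_per_study = c(2, 5), beta = 0.2,
                    sigma2_study = 0.05, sigma2_trait = 0.02,
                    sigma2_taxon = 0.01, seed = 42)
  es <- compute_effect_sizes(simulate_dataset(cfg)$records, "g", quiet = TRUE)
  f <- reml_mv(es, random = c("study", "trait", "taxon"))
  m <- metafor::rma.mv(yi, vi,
                       random = list(~ 1 | study_id, ~ 1 | trait, ~ 1 | taxon),
                       data = es, method = "REML")
  expect_equal(unname(f$beta), unname(stats::coef(m)), tolerance = 1e-5)
  expect_equal(unname(f$se), unname(m$se), tolerance = 1e-5)
  expect_equal(unname(f$sigma2), unname(m$sigma2), tolerance = 1e-4)

  # with a moderator
  f2 <- reml_mv(es, mods = ~ sex, random = c("study", "trait"))
  m2 <- metafor::rma.mv(yi, vi, mods = ~ sex,
                        random = list(~ 1 | study_id, ~ 1 | trait),
                        data = transform(es, sex = factor(sex, c("male", "female", "both"))),
                        method = "REML")
  expect_equal(unname(f2$beta), unname(stats::coef(m2)), tolerance = 1e-5)
})

test_that("the moderator design uses treatment coding with male/benign reference", {
  cfg <- sim_config(n_studies = 30, effects_per_study = c(3, 6),
                    beta = c(0.2, 0.1, 0, -0.15, 0.25, 0.2), seed = 3)
  d <- simulate_dataset(cfg)$records
  des <- build_design(d, ~ sex * environment,
                      random = c("study", "trait", "taxon"))
  expect_equal(ncol(des$X), 6)
  expect_equal(colnames(des$X)[1], "(Intercept)")
  expect_true(all(c("sexfemale", "sexboth", "environmentstressful",
                    "sexfemale:environmentstressful",
                    "sexboth:environmentstressful") %in% colnames(des$X)))
  # reference cell rows are all-zero beyond the intercept
  ref <- d$sex == "male" & d$environment == "benign"
  expect_true(all(des$X[ref, -1] == 0))
  expect_equal(length(des$Z), 3)
  expect_error(build_design(d, ~ nonexistent_column), "unknown moderator")
  d2 <- d
  d2$sex_copy <- d2$sex
  expect_error(build_design(d2, ~ sex + sex_copy), "aliased")
})

test_that("contrasts satisfy the Wald identities", {
  set.seed(55)
  k <- 60
  d <- data.frame(study_id = paste0("s", rep(1:15, 4)),
                  grp = sample(c("a", "b", "c"), k, replace = TRUE))
  vi <- stats::runif(k, 0.05, 0.2)
  yi <- toy_meta_sample(k, 0.2, 0.05, vi) + (d$grp == "b") * 0.3
  f <- reml_mv(yi, vi, mods = ~ grp, random = "study", data = d)
  L <- c(0, 1, -1)
  ct <- contrast(f, L)
  expect_equal(ct$estimate, sum(L * f$beta))
  expect_equal(ct$se, sqrt(drop(t(L) %*% f$vb %*% L)))
  expect_equal(ct$ci95, ct$estimate + c(-1.96, 1.96) * ct$se)
  expect_equal(contrast(f, c(0, 0, 0))$estimate, 0)
  expect_error(contrast(f, c(1, 0)), "length")
})

test_that("per-level predictions recover known class means", {
  set.seed(66)
  k <- 240
  d <- data.frame(study_id = paste0("s", rep(1:40, 6)),
                  fitness_class = rep(c("direct", "indirect", "ambiguous"),
                                      each = 80))
  truth <- c(ambiguous = 0.21, direct = 0.13, indirect = 0.24)
  vi <- stats::runif(k, 0.02, 0.1)
  yi <- truth[d$fitness_class] + stats::rnorm(k, 0, sqrt(vi)) +
    stats::rnorm(40, 0, sqrt(0.02))[rep(1:40, 6)]
  f <- reml_mv(yi, vi, mods = ~ fitness_class, random = "study", data = d)
  pr <- predict_levels(f)
  expect_equal(nrow(pr), 3)
  for (i in seq_len(3)) {
    cls <- as.character(pr$fitness_class[i])
    expect_lt(abs(pr$estimate[i] - truth[[cls]]), 2 * pr$se[i] + 0.02)
  }
  expect_error(predict_levels(f, data.frame(fitness_class = "unknown")),
               "unknown level")
  # intercept-only model predicts its own coefficient
  f0 <- reml_mv(yi, vi, random = "study", data = d)
  expect_equal(predict_levels(f0)$estimate, unname(f0$beta[1]))
})

test_that("per-trait models respect the minimum-size threshold", {
  cfg <- sim_config(n_studies = 25, effects_per_study = c(2, 4),
                    trait_labels = c("t1", "t2", "t3"), seed = 12)
  es <- compute_effect_sizes(simulate_dataset(cfg)$records, "g", quiet = TRUE)
  rare <- make_record(study_id = "sx", trait = "rare")
  es_rare <- compute_effect_sizes(rbind(rare, rare, rare), "g", quiet = TRUE)
  es_rare$study_id <- paste0("sx", 1:3)
  both <- rbind(es, es_rare)
  out <- per_trait_models(both)
  expect_true("rare" %in% out$skipped)       # exactly 3 effects: skipped
  expect_true(all(c("t1", "t2", "t3") %in% names(out$fits)))
  # a single-trait dataset reproduces a direct intercept-only fit
  sub <- es[es$trait == "t1", ]
  direct <- reml_mv(sub, random = c("study", "taxon"))
  expect_equal(out$fits[["t1"]]$beta, direct$beta, tolerance = 1e-8)
})
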