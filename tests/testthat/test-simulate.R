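test_that("identical config and seed give identical datasets", {
  cfg <- sim_config(n_studies = 20, seed = 99)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1, d2)
  d3 <- simulate_dataset(sim_config(n_studies = 20, seed = 100))
  expect_false(identical(d1$records, d3$records))
})

test_that("noise-free limit recovers the true effect", {
  # all variance components zero and enormous groups: every computed g
  # must sit at the true standardised difference
  cfg <- sim_config(n_studies = 10, effects_per_study = c(2, 2), beta = 0.3,
                    sigma2_study = 0, sigma2_trait = 0, sigma2_taxon = 0,
                    group_n_range = c(1e6, 1e6), seed = 11)
  es <- compute_effect_sizes(simulate_dataset(cfg)$records, "g", quiet = TRUE)
  expect_equal(nrow(es), 20)
  expect_true(all(abs(es$yi - 0.3) < 0.02))
})

test_that("sampled level deviations have the configured variance", {
  cfg <- sim_config(n_studies = 3000, effects_per_study = c(1, 1),
                    sigma2_study = 0.04, seed = 21)
  ds <- simulate_dataset(cfg)
  expect_equal(stats::var(ds$truth$u_study), 0.04, tolerance = 0.15)
  # per-record true effects decompose as fixed part + the level deviations
  r <- ds$records
  th <- 0.2 + ds$truth$u_study[r$study_id] + ds$truth$u_trait[r$trait] +
    ds$truth$u_taxon[r$taxon]
  expect_equal(unname(th), unname(ds$truth$theta))
})

test_that("with no heterogeneity the spread of g matches its sampling variance", {
  cfg <- sim_config(n_studies = 400, effects_per_study = c(1, 1), beta = 0.25,
                    sigma2_study = 0, sigma2_trait = 0, sigma2_taxon = 0,
                    group_n_range = c(30, 30), seed = 31)
  es <- compute_effect_sizes(simulate_dataset(cfg)$records, "g", quiet = TRUE)
  expect_equal(stats::var(es$yi), mean(es$vi), tolerance = 0.2)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(sigma2_study = -1), "non-negative")
  expect_error(sim_config(group_n_range = c(1, 10)), "min >= 2")
  expect_error(sim_config(effects_per_study = c(5, 2)), "increasing")
  expect_error(sim_config(cv_range = c(-0.1, 0.3)), "positive")
  expect_error(sim_config(beta = c(1, 2)), "length 1")
  probs <- c(male.benign = 0.5, female.benign = 0.5, both.benign = 0.5,
             male.stressful = 0, female.stressful = 0, both.stressful = 0)
  expect_error(sim_config(moderator_probs = probs), "sum to 1")
})

test_that("configs round-trip through YAML", {
  cfg <- sim_config(n_studies = 12, beta = 0.15, seed = 5)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(cfg), path)
  cfg2 <- read_sim_config(path)
  expect_equal(unclass(cfg2), unclass(cfg), tolerance = 1e-12)
})

test_that("the full-synthesis dataset has the documented shape", {
  ds <- simulate_paperlike(seed = 4)
  r <- ds$records
  expect_equal(nrow(r), 459)
  expect_equal(length(unique(r$study_id)), 65)
  expect_equal(length(unique(r$trait)), 22)
  expect_equal(length(unique(r$taxon)), 7)
  expect_equal(as.integer(table(r$sex)[c("male", "female", "both")]),
               c(189L, 219L, 51L))
  expect_equal(as.integer(table(r$environment)[c("stressful", "benign", "undefined")]),
               c(92L, 337L, 30L))
  expect_equal(as.integer(table(r$fitness_class)[c("direct", "indirect", "ambiguous")]),
               c(174L, 141L, 144L))
  expect_equal(sum(r$input_kind == "summaries"), 354)
  expect_true(all(table(r$study_id) >= 1) && all(table(r$study_id) <= 30))
  # reproducible record-level table; different seeds reshuffle
  expect_identical(r, simulate_paperlike(seed = 4)$records)
  expect_false(identical(r, simulate_paperlike(seed = 5)$records))
  # every seed keeps the marginal counts
  r2 <- simulate_paperlike(seed = 123)$records
  expect_equal(nrow(r2), 459)
  expect_equal(length(unique(r2$study_id)), 65)
})

test_that("statistic-only records reproduce the g of their source summaries", {
  # the generator converts summary draws to t statistics for records
  # without summaries; the resulting g must follow the same distribution,
  # so a record's t-based g equals the g its summaries would have given
  ds <- simulate_paperlike(seed = 8)
  r <- ds$records
  es <- compute_effect_sizes(r, "g", quiet = TRUE)
  expect_equal(nrow(es), 459)
  expect_true(all(is.finite(es$yi)) && all(es$vi > 0))
})
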