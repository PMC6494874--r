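# Converter oracles below were evaluated by hand from the defining
# formulas (pooled SD, J = 1 - 3/(4 df - 1), variance formulas) and frozen.

expect_sig <- function(x, expected, sig = 6) {
  expect_equal(x, expected, tolerance = 10^(-sig))
}

test_that("Hedges' g from summaries matches the hand-evaluated oracle", {
  es <- hedges_g(1.5, 0.5, 20, 1.0, 0.5, 20)
  # d = 0.5/0.5 = 1 exactly; J = 148/151
  expect_sig(es$detail$d, 1)
  expect_sig(es$detail$J, 148 / 151)
  expect_equal(es$detail$df, 38)
  expect_sig(es$value, 148 / 151)
  expect_sig(es$variance, (148 / 151)^2 * (40 / 400 + 1 / 80))
  expect_equal(hedges_g(1, 0.3, 10, 1, 0.3, 12)$value, 0)  # identical means
})

test_that("g converters from test statistics match hand-evaluated oracles", {
  es_t <- g_from_t(2, 20, 20)
  expect_sig(es_t$detail$d, 2 * sqrt(40 / 400))
  expect_sig(es_t$value, 0.619890190337643)
  expect_equal(g_from_t(0, 15, 18)$value, 0)

  es_f <- g_from_f(4, 20, 20, direction = -1)
  expect_sig(es_f$detail$d, -2 * sqrt(40 / 400))
  expect_sig(es_f$value, -es_t$value)

  es_c <- g_from_chisq(3.84, 50, 50, direction = 1)
  r <- sqrt(3.84 / 100)
  expect_sig(es_c$detail$d, 2 * r / sqrt(1 - r^2))
  expect_sig(es_c$detail$d, 0.399667221842103)
})

test_that("proportion conversion applies the Cox logit and continuity rule", {
  logit <- function(p) log(p / (1 - p))
  es <- g_from_proportions(0.8, 0.5, 30, 30)
  expect_sig(es$detail$d, (logit(0.8) - logit(0.5)) / 1.65)
  expect_equal(g_from_proportions(0.4, 0.4, 25, 25)$value, 0)
  # p = 1: numerator reduced by one before the logit
  es1 <- g_from_proportions(1, 0.5, 20, 20)
  expect_sig(es1$detail$d, (logit(19 / 20) - logit(0.5)) / 1.65)
  # p = 0: numerator raised by one
  es0 <- g_from_proportions(0.5, 0, 20, 20)
  expect_sig(es0$detail$d, (logit(0.5) - logit(1 / 20)) / 1.65)
  expect_error(g_from_proportions(1, 0.5, NA, 20))
  expect_error(g_from_proportions(1.2, 0.5, 20, 20), "0, 1")
})

test_that("ratio measures match hand-evaluated oracles", {
  es <- lnrr(2, 0.5, 10, 1, 0.5, 10)
  expect_sig(es$value, log(2))
  expect_sig(es$variance, 0.03125)

  es <- lncvr(2, 0.2, 20, 1.5, 0.3, 20)   # CV_h = 0.1, CV_l = 0.2
  expect_sig(es$value, log(0.5))
  expect_sig(es$variance, 0.0005 + 1 / 38 + 0.002 + 1 / 38)
  # rho shifts the variance by the covariance terms
  v0 <- lncvr(2, 0.2, 20, 1.5, 0.3, 20, rho = 0)$variance
  v5 <- lncvr(2, 0.2, 20, 1.5, 0.3, 20, rho = 0.5)$variance
  expect_sig(v0 - v5, 2 * 0.5 * (sqrt(0.0005) * sqrt(1 / 38) +
                                   sqrt(0.002) * sqrt(1 / 38)))

  es <- lnvr(2, 10, 1, 10)
  expect_sig(es$value, log(2))     # equal n: corrections cancel
  expect_sig(es$variance, 1 / 9)
  expect_equal(lnvr(1.3, 12, 1.3, 12)$value, 0)
})

test_that("all measures are antisymmetric under group swap at equal n", {
  cases <- list(c(2.4, 0.7, 18, 1.9, 0.5, 18),
                c(5.0, 1.2, 30, 6.1, 1.8, 30))
  for (cs in cases) {
    a <- do.call(hedges_g, as.list(cs))
    b <- do.call(hedges_g, as.list(cs[c(4:6, 1:3)]))
    expect_sig(b$value, -a$value); expect_sig(b$variance, a$variance)
    for (fn in list(lnrr, lncvr)) {
      a <- do.call(fn, as.list(cs)); b <- do.call(fn, as.list(cs[c(4:6, 1:3)]))
      expect_sig(b$value, -a$value)
    }
    a <- lnvr(cs[2], cs[3], cs[5], cs[6]); b <- lnvr(cs[5], cs[6], cs[2], cs[3])
    expect_sig(b$value, -a$value)
  }
})

test_that("g from a back-computed t equals g from summaries (equal n)", {
  m_h <- 3.2; s_h <- 1.1; m_l <- 2.7; s_l <- 0.9; n <- 24
  sp <- sqrt(((n - 1) * s_h^2 + (n - 1) * s_l^2) / (2 * n - 2))
  t <- (m_h - m_l) / (sp * sqrt(2 / n))
  a <- hedges_g(m_h, s_h, n, m_l, s_l, n)
  b <- g_from_t(t, n, n)
  expect_sig(b$value, a$value)
  expect_sig(b$variance, a$variance)
})

test_that("sampling variances are positive and decrease in both group sizes", {
  ns <- c(5, 10, 20, 40, 80)
  for (fn in list(
    function(n1, n2) hedges_g(1.4, 0.5, n1, 1.0, 0.5, n2)$variance,
    function(n1, n2) lnrr(1.4, 0.5, n1, 1.0, 0.5, n2)$variance,
    function(n1, n2) lncvr(1.4, 0.5, n1, 1.0, 0.5, n2)$variance,
    function(n1, n2) lnvr(0.5, n1, 0.5, n2)$variance)) {
    v_n1 <- sapply(ns, fn, n2 = 15)
    v_n2 <- sapply(ns, fn, n1 = 15)
    expect_true(all(v_n1 > 0) && all(diff(v_n1) < 0))
    expect_true(all(v_n2 > 0) && all(diff(v_n2) < 0))
  }
})

test_that("converters agree with metafor's escalc", {
  skip_if_not_installed("metafor")
  g <- hedges_g(1.5, 0.5, 20, 1.0, 0.5, 18)
  e <- metafor::escalc("SMD", m1i = 1.5, m2i = 1.0, sd1i = 0.5, sd2i = 0.5,
                       n1i = 20, n2i = 18)
  # metafor applies the exact gamma-ratio bias correction; the
  # 1 - 3/(4 df - 1) approximation agrees to ~1e-4 at these sizes
  expect_equal(g$value, as.numeric(e$yi), tolerance = 1e-3)

  rr <- lnrr(2.2, 0.6, 14, 1.7, 0.5, 11)
  e <- metafor::escalc("ROM", m1i = 2.2, m2i = 1.7, sd1i = 0.6, sd2i = 0.5,
                       n1i = 14, n2i = 11)
  expect_equal(rr$value, as.numeric(e$yi), tolerance = 1e-8)
  expect_equal(rr$variance, as.numeric(e$vi), tolerance = 1e-8)

  vr <- lnvr(0.8, 16, 0.5, 16)  # equal n so bias corrections coincide
  e <- metafor::escalc("VR", m1i = 1, m2i = 1, sd1i = 0.8, sd2i = 0.5,
                       n1i = 16, n2i = 16)
  expect_equal(vr$value, as.numeric(e$yi), tolerance = 1e-8)
  expect_equal(vr$variance, as.numeric(e$vi), tolerance = 1e-8)

  cv <- lncvr(2.0, 0.4, 16, 1.5, 0.45, 16)
  e <- metafor::escalc("CVR", m1i = 2.0, m2i = 1.5, sd1i = 0.4, sd2i = 0.45,
                       n1i = 16, n2i = 16)
  expect_equal(cv$value, as.numeric(e$yi), tolerance = 1e-8)
  expect_equal(cv$variance, as.numeric(e$vi), tolerance = 1e-8)
})

test_that("degenerate inputs are rejected", {
  expect_error(hedges_g(1, 0, 10, 1, 0, 10), "pooled SD")
  expect_error(hedges_g(1, 0.5, 1, 1, 0.5, 10), ">= 2")
  expect_error(lnrr(-1, 0.5, 10, 1, 0.5, 10), "positive means")
  expect_error(lncvr(1, 0, 10, 1, 0.5, 10), "positive SDs")
  expect_error(lnvr(0, 10, 0.5, 10), "positive SDs")
  expect_error(g_from_f(2, 20, 20, df1 = 2), "not supported")
  expect_error(g_from_chisq(2, 20, 20, df = 3), "not supported")
})

test_that("compute_effect_sizes dispatches, orients and counts skips", {
  recs <- rbind(
    make_record(study_id = "a", trait = "lifespan"),
    make_record(study_id = "b", trait = "extinction rate",
                negatively_related = TRUE),
    make_record(study_id = "c", input_kind = "t", statistic_value = 2,
                m_high = NA, s_high = NA, m_low = NA, s_low = NA),
    make_record(study_id = "d", m_high = -0.5, m_low = 1)  # lnRR impossible
  )
  g <- compute_effect_sizes(recs, "g", quiet = TRUE)
  expect_equal(nrow(g), 4)
  # raw g of row b is positive (means 1.5 vs 1.0) but the trait is
  # negatively related, so the oriented effect is negative
  expect_lt(g$yi[g$study_id == "b"], 0)
  expect_equal(g$yi[g$study_id == "b"], -g$yi[g$study_id == "a"])

  rr <- compute_effect_sizes(recs, "lnRR", quiet = TRUE)
  expect_equal(nrow(rr), 2)  # t-record and negative-mean record skipped
  expect_equal(attr(rr, "n_skipped"), 2)
  cv <- compute_effect_sizes(recs, "lnCVR", quiet = TRUE)
  expect_equal(nrow(cv), 2)  # negative mean also blocks the CV ratio
  vr <- compute_effect_sizes(recs, "lnVR", quiet = TRUE)
  expect_equal(nrow(vr), 3)  # lnVR only needs SDs, so the negative mean is fine
})
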