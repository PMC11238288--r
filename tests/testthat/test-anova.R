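anova_row <- function(a, src) a[a$source == src, ]

# agreement with a value printed at 2 decimal places
expect_2dp <- function(actual, printed) {
  expect_lt(abs(actual - printed), 0.0051)
}

test_that("chlorophyll ANOVA reproduces the reported decomposition", {
  a <- anova(fit_chl)

  expect_2dp(anova_row(a, "model")$adj_ss, 14.94)
  expect_2dp(anova_row(a, "model")$f_value, 170.55)
  expect_2dp(anova_row(a, "linear")$adj_ss, 3.44)
  expect_2dp(anova_row(a, "time")$adj_ss, 2.63)
  expect_2dp(anova_row(a, "time")$f_value, 270.55)
  expect_2dp(anova_row(a, "amplitude")$f_value, 80.04)
  # type-III adjusted SS for the pure quadratic terms
  expect_2dp(anova_row(a, "square")$adj_ss, 8.20)
  expect_2dp(anova_row(a, "time^2")$adj_ss, 4.16)
  expect_2dp(anova_row(a, "amplitude^2")$adj_ss, 5.54)
  expect_2dp(anova_row(a, "temperature^2")$adj_ss, 0.13)
  expect_2dp(anova_row(a, "amplitude:temperature")$adj_ss, 2.82)
  expect_2dp(anova_row(a, "amplitude:temperature")$f_value, 289.85)
  expect_2dp(anova_row(a, "pure error")$adj_ss, 0.05)
  expect_2dp(anova_row(a, "lack-of-fit")$p_value, 0.570)
  expect_2dp(anova_row(a, "total")$adj_ss, 15.03)

  expect_2dp(100 * attr(a, "r.squared"), 99.35)
  expect_2dp(100 * attr(a, "adj.r.squared"), 98.77)
  expect_2dp(100 * attr(a, "pred.r.squared"), 97.26)
})

test_that("ascorbic-acid ANOVA reproduces the reported decomposition", {
  a <- anova(fit_aa)
  expect_2dp(anova_row(a, "model")$f_value, 114.56)
  expect_2dp(anova_row(a, "time")$adj_ss, 1110.39)
  expect_2dp(anova_row(a, "temperature^2")$adj_ss, 345.86)
  expect_2dp(anova_row(a, "lack-of-fit")$f_value, 4.68)
  expect_2dp(100 * attr(a, "r.squared"), 99.04)
  expect_2dp(100 * attr(a, "pred.r.squared"), 93.37)
})

test_that("ANOVA bookkeeping holds on random synthetic tables", {
  set.seed(202)
  for (i in 1:20) {
    beta <- random_quadratic_beta()
    tab <- simulate_ccd_response(beta, pj_factors,
                                 noise_sd = runif(1, 0.02, 0.5))
    fit <- rsm(y ~ time + amplitude + temperature, tab, pj_factors)
    a <- anova(fit)
    ss <- function(src) anova_row(a, src)$adj_ss
    df <- function(src) anova_row(a, src)$df
    expect_equal(ss("model") + ss("error"), ss("total"), tolerance = 1e-8)
    expect_equal(ss("lack-of-fit") + ss("pure error"), ss("error"),
                 tolerance = 1e-8)
    expect_equal(df("model") + df("error"), df("total"))
    expect_equal(df("total"), nrow(tab) - 1L)
    expect_equal(df("lack-of-fit") + df("pure error"), df("error"))
    # R-squared ordering
    expect_lte(attr(a, "adj.r.squared"), attr(a, "r.squared"))
    expect_lte(attr(a, "pred.r.squared"), attr(a, "r.squared"))
  }
})

test_that("noise-free data give a saturated decomposition", {
  tab <- simulate_ccd_response(truth_beta, pj_factors, noise_sd = 0)
  fit <- rsm(y ~ time + amplitude + temperature, tab, pj_factors)
  a <- anova(fit)
  expect_lt(anova_row(a, "error")$adj_ss, 1e-16)
  expect_equal(attr(a, "r.squared"), 1, tolerance = 1e-12)
})

test_that("first-order ANOVA has no square or interaction sources", {
  a <- anova(fit_chl_mlr)
  expect_false(any(grepl("\\^2|:", a$source)))
  expect_equal(anova_row(a, "model")$df, 3L)
  expect_equal(anova_row(a, "model")$adj_ss + anova_row(a, "error")$adj_ss,
               anova_row(a, "total")$adj_ss, tolerance = 1e-8)
})
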