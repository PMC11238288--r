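test_that("coefficients equal their orthogonal-contrast estimates", {
  # the coded CCD is orthogonal for linear and interaction columns, so OLS
  # coefficients must equal the independent contrast oracle sum(x*y)/sum(x^2)
  cd <- attr(pj, "coded")
  y <- pj$chlorophyll
  b <- coef(fit_chl)
  for (j in 1:3)
    expect_equal(unname(b[1 + j]), sum(cd[, j] * y) / sum(cd[, j]^2),
                 tolerance = 1e-10)
  pairs <- combn(3, 2)
  for (q in 1:3) {
    x <- cd[, pairs[1, q]] * cd[, pairs[2, q]]
    expect_equal(unname(b[7 + q]), sum(x * y) / sum(x^2), tolerance = 1e-10)
  }
  # same property on a synthetic table
  tab <- simulate_ccd_response(truth_beta, pj_factors, noise_sd = 0.3,
                               seed = 11)
  f2 <- rsm(y ~ time + amplitude + temperature, tab, pj_factors)
  cd2 <- to_coded(as.matrix(tab[names(pj_factors)]), pj_factors)
  for (j in 1:3)
    expect_equal(unname(coef(f2)[1 + j]),
                 sum(cd2[, j] * tab$y) / sum(cd2[, j]^2), tolerance = 1e-10)
})

test_that("fitted chlorophyll surface reproduces reported spot predictions", {
  # centre prediction and the amplitude:temperature interaction
  expect_equal(unname(predict(fit_chl, c(8, 80, 50))), 7.53, tolerance = 0.005)
  expect_equal(unname(coef(fit_chl)["amplitude:temperature"]), 0.59375,
               tolerance = 1e-8)
  expect_equal(unname(predict(fit_chl, c(8, 80, 40))), 7.33, tolerance = 0.005)
  expect_equal(unname(predict(fit_aa, c(4, 80, 50))), 121.70, tolerance = 0.005)
})

test_that("a noise-free quadratic is interpolated exactly", {
  tab <- simulate_ccd_response(truth_beta, pj_factors, noise_sd = 0)
  fit <- rsm(y ~ time + amplitude + temperature, tab, pj_factors)
  expect_equal(unname(coef(fit)), truth_beta, tolerance = 1e-8)
  expect_lt(sum(residuals(fit)^2), 1e-16)
})

test_that("refitting on the model's own predictions is idempotent", {
  tab <- pj
  tab$chlorophyll <- fitted(fit_chl)
  refit <- rsm(chlorophyll ~ time + amplitude + temperature, tab, pj_factors)
  expect_equal(coef(refit), coef(fit_chl), tolerance = 1e-10)
})

test_that("first-order fit is affine and centred on the grand mean", {
  # prediction at the design centre of an OLS first-order fit to a balanced
  # design must be the grand mean of the response
  expect_equal(unname(predict(fit_chl_mlr, c(8, 80, 50))),
               mean(pj$chlorophyll), tolerance = 1e-10)
  # the experiment reported 6.76 at the centre; OLS on all 20 runs gives 6.78
  expect_equal(unname(predict(fit_chl_mlr, c(8, 80, 50))), 6.76,
               tolerance = 0.05)
  # affine: equal slope between any level pair
  d1 <- predict(fit_chl_mlr, c(6, 80, 50)) - predict(fit_chl_mlr, c(4, 80, 50))
  d2 <- predict(fit_chl_mlr, c(12, 80, 50)) - predict(fit_chl_mlr, c(10, 80, 50))
  expect_equal(d1, d2, tolerance = 1e-10)
})

test_that("prediction at the centre equals the intercept for any surface", {
  for (fit in list(fit_chl, fit_aa, fit_chl_mlr))
    expect_equal(unname(predict(fit, c(8, 80, 50))),
                 unname(coef(fit)[1]), tolerance = 1e-12)
})

test_that("degenerate fits are rejected and extrapolation is flagged", {
  centres <- pj[pj$time == 8 & pj$amplitude == 80 & pj$temperature == 50, ]
  expect_error(rsm(chlorophyll ~ time + amplitude + temperature, centres,
                   pj_factors), "runs|singular")
  expect_error(rsm(chlorophyll ~ time + amplitude + temperature, pj,
                   pj_factors, order = 3), "order")
  expect_error(rsm(chlorophyll ~ time + amplitude + missing_col, pj,
                   pj_factors), "missing_col")
  expect_warning(predict(fit_chl, c(20, 80, 50)), "outside")
})

test_that("simulate() from a fit is seeded and centred on the fitted values", {
  s1 <- simulate(fit_chl, nsim = 2, seed = 9)
  s2 <- simulate(fit_chl, nsim = 2, seed = 9)
  expect_identical(s1, s2)
  s0 <- simulate(fit_chl, nsim = 1, seed = 1, noise_sd = 0)
  expect_equal(s0[[1]], unname(fitted(fit_chl)))
})
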