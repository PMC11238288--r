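test_that("reported optimum condition evaluates to the published predictions", {
  v <- parsley_validation()
  pt <- c(v$time, v$amplitude, v$temperature)
  expect_equal(unname(predict(fit_chl, pt)), 7.79, tolerance = 0.05)
  expect_equal(unname(predict(fit_aa, pt)), 145.42, tolerance = 0.05)
})

test_that("percent difference uses the prediction as denominator", {
  expect_equal(percent_difference(7.79, 7.34), 5.78, tolerance = 0.005)
  expect_equal(percent_difference(145.42, 139.23), 4.26, tolerance = 0.005)
  expect_equal(percent_difference(5, 5), 0)
  expect_error(percent_difference(0, 1), "zero")
})

test_that("constrained chlorophyll optimum sits on the temperature floor", {
  opt <- optimize_response(fit_chl, seed = 12)
  expect_equal(unname(opt$best_natural["temperature"]), 40, tolerance = 1e-6)
  # gradient in temperature is negative there, so the bound is active:
  # d/dx3 at the optimum = b3 + 2*b33*x3 + b13*x1 + b23*x2 < 0
  b <- coef(fit_chl)
  cd <- opt$best_coded
  grad3 <- b["temperature"] + 2 * b["temperature^2"] * cd["temperature"] +
    b["time:temperature"] * cd["time"] +
    b["amplitude:temperature"] * cd["amplitude"]
  expect_lt(unname(grad3), 0)
})

test_that("optimum object is self-consistent and within bounds", {
  for (seed in c(1, 5)) {
    opt <- optimize_response(fit_aa, seed = seed)
    expect_equal(opt$best_predicted,
                 unname(predict(fit_aa, opt$best_natural)), tolerance = 1e-12)
    expect_true(all(opt$best_natural >= opt$lower - 1e-9 &
                    opt$best_natural <= opt$upper + 1e-9))
    expect_equal(unname(to_natural(opt$best_coded, pj_factors)),
                 unname(opt$best_natural), tolerance = 1e-9)
  }
})

test_that("PSO is sandwiched between grid and analytic optima on quadratics", {
  # analytic oracle: multi-start box-constrained quasi-Newton on the surface
  analytic_best <- function(fit, lo, hi) {
    starts <- rbind(c(8, 80, 50), c(5, 65, 42), c(11, 95, 58), c(6, 90, 45))
    best <- -Inf
    for (i in seq_len(nrow(starts))) {
      o <- optim(starts[i, ], function(p) -predict(fit, p),
                 method = "L-BFGS-B", lower = lo, upper = hi)
      best <- max(best, -o$value)
    }
    best
  }
  lo <- c(4, 60, 40); hi <- c(12, 100, 60)
  for (fit in list(fit_chl, fit_aa)) {
    ref <- analytic_best(fit, lo, hi)
    g <- grid_search(fit, lo, hi, n = 101)
    p <- optimize_response(fit, lo, hi, seed = 8)
    expect_gte(p$best_predicted, g$best_predicted - 0.01)
    expect_lte(p$best_predicted, ref + 1e-9)
    expect_lte(g$best_predicted, ref + 1e-9)
  }
})

test_that("grid search recovers lattice vertices and refuses huge lattices", {
  # interior vertex placed on the lattice
  fn <- function(p) -sum((p - c(0.5, 0.25))^2)
  g <- grid_search(fn, lower = c(0, 0), upper = c(1, 1), n = 5)
  expect_equal(unname(g$best_natural), c(0.5, 0.25))
  expect_equal(g$best_predicted, 0)
  # monotone linear surface maximized at a corner
  g2 <- grid_search(function(p) sum(p), lower = c(0, 0), upper = c(2, 3),
                    n = 11)
  expect_equal(unname(g2$best_natural), c(2, 3))
  expect_error(grid_search(fn, c(0, 0), c(1, 1), n = 1e5), "too large")
  expect_error(grid_search(fn, c(0, 0), c(1, 1), n = 1), ">= 2")
})
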