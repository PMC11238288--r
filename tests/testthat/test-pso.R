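test_that("inertia weight interpolates linearly between its endpoints", {
  expect_equal(inertia_weight(0, 50), 1.0)
  expect_equal(inertia_weight(50, 50), 0.1)
  expect_equal(inertia_weight(25, 50), (1.0 + 0.1) / 2)
  expect_equal(inertia_weight(10, 40, w_start = 0.9, w_end = 0.4),
               0.9 - 0.5 / 4)
  expect_error(inertia_weight(-1, 50), "k")
  expect_error(inertia_weight(51, 50), "k")
})

test_that("velocity rule matches hand evaluation and limiting cases", {
  # scalar: w=0.5, v=1, x=0, pbest=2, sbest=4, c1=c2=0.5, r1=r2=0.5
  v <- pso_velocity(v = 1, x = 0, pbest = 2, sbest = 4, w = 0.5,
                    c1 = 0.5, c2 = 0.5, r1 = 0.5, r2 = 0.5)
  expect_equal(v, 0.5 + 0.5 + 1.0)
  expect_equal(0 + v, 2.0)  # position update
  # free drift: w=1, no attraction
  expect_equal(pso_velocity(c(1, -2), c(0, 0), c(5, 5), c(9, 9),
                            w = 1, c1 = 0, c2 = 0, r1 = 1, r2 = 1),
               c(1, -2))
  # at both bests: only momentum remains
  expect_equal(pso_velocity(3, 7, 7, 7, w = 0.4, c1 = 2, c2 = 2,
                            r1 = 0.9, r2 = 0.9), 1.2)
})

test_that("swarm finds the unique maximum of a concave quadratic", {
  m <- c(1.5, -2, 0.5)
  fn <- function(p) -sum((p - m)^2)
  out <- pso(fn, lower = rep(-5, 3), upper = rep(5, 3), seed = 4)
  expect_equal(out$par, m, tolerance = 1e-2)
  expect_equal(out$value, 0, tolerance = 1e-3)
})

test_that("identical seeds reproduce the run bit-for-bit", {
  fn <- function(p) -sum(p^2) + sum(p)
  a <- pso(fn, c(-3, -3), c(3, 3), seed = 77)
  b <- pso(fn, c(-3, -3), c(3, 3), seed = 77)
  expect_identical(a$trace, b$trace)
  expect_identical(a$par, b$par)
  c_ <- pso(fn, c(-3, -3), c(3, 3), seed = 78)
  expect_false(identical(a$trace, c_$trace))
})

test_that("trace is monotone and solutions feasible on random quadratics", {
  set.seed(31)
  for (i in 1:8) {
    beta <- random_quadratic_beta()
    tab <- simulate_ccd_response(beta, pj_factors, noise_sd = 0)
    fit <- rsm(y ~ time + amplitude + temperature, tab, pj_factors)
    lo <- c(4, 60, 40); hi <- c(12, 100, 60)
    out <- pso(function(p) predict(fit, p), lo, hi,
               control = pso_control(n_particles = 20, n_iter = 25),
               seed = i)
    expect_true(all(diff(out$trace) >= 0))
    expect_true(all(out$par >= lo - 1e-12 & out$par <= hi + 1e-12))
    # the trace ends at the reported best
    expect_equal(out$trace[length(out$trace)], out$value)
  }
})

test_that("minimization negates the maximization machinery consistently", {
  fn <- function(p) sum((p - 1)^2)
  out <- pso(fn, c(-4, -4), c(4, 4), seed = 2, maximize = FALSE)
  expect_equal(out$par, c(1, 1), tolerance = 1e-2)
  expect_true(all(diff(out$trace) <= 0))  # best value decreases
})

test_that("invalid configurations fail before any evaluation", {
  expect_error(pso_control(n_particles = 0), "n_particles")
  expect_error(pso_control(c1 = -1), "non-negative")
  expect_error(pso_control(w_start = 1.5), "inertia")
  expect_error(pso(function(p) 1, lower = c(0, 0), upper = c(0, 1)),
               "lower < upper")
  expect_error(pso(function(p) 1, lower = c(0), upper = c(1, 2)),
               "equal length")
})

test_that("non-finite fitness values are rejected with a warning", {
  fn <- function(p) if (p[1] > 0.5) NaN else sum(p)
  expect_warning(
    out <- pso(fn, c(0, 0), c(1, 1),
               control = pso_control(n_particles = 10, n_iter = 5), seed = 1),
    "non-finite")
  expect_true(is.finite(out$value))
})
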