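#' Optimize a fitted response surface over a natural-unit box
#'
#' Maximizes (by default) the model's predicted response over bound
#' constraints on the natural factor scale, either with the particle swarm
#' of [pso()] or by exhaustive lattice search via [grid_search()]. The
#' default bounds are the factor design ranges used in the packaged
#' experiment: time 4–12 min, amplitude 60–100%, temperature 40–60 degC
#' (each factor's centre +/- 2 steps).
#'
#' @param object A fitted `"rsm"` model.
#' @param lower,upper Natural-unit bounds, one entry per factor; defaults to
#'   centre +/- 2 steps.
#' @param method `"pso"` or `"grid"`.
#' @param control [pso_control()] settings (PSO only).
#' @param seed Integer seed for the swarm (PSO only).
#' @param n_grid Lattice points per dimension (grid only).
#' @param maximize Direction of optimization.
#'
#' @return An object of class `"response_optimum"`: the optimizing point in
#'   natural and coded units, the predicted response there, the method and
#'   seed, and (for PSO) the convergence trace.
#' @examples
#' pj <- parsley_juice()
#' fit <- rsm(chlorophyll ~ time + amplitude + temperature,
#'            data = pj, factors = parsley_factors())
#' optimize_response(fit, seed = 1)
#' @export
optimize_response <- function(object, lower = NULL, upper = NULL,
                              method = c("pso", "grid"),
                              control = pso_control(), seed = NULL,
                              n_grid = 201, maximize = TRUE) {
  stopifnot(inherits(object, "rsm"))
  method <- match.arg(method)
  b <- default_bounds(object, lower, upper)

  if (method == "pso") {
    run <- pso(function(p) predict(object, p), b$lower, b$upper,
               control = control, seed = seed, maximize = maximize)
    best <- run$par
    value <- run$value
    trace <- run$trace
  } else {
    gs <- grid_search(object, b$lower, b$upper, n = n_grid,
                      maximize = maximize)
    best <- gs$best_natural
    value <- gs$best_predicted
    trace <- NULL
  }
  names(best) <- names(object$factors)

  structure(list(
    response = object$response,
    model_order = object$order,
    best_natural = best,
    best_coded = to_coded(best, object$factors),
    best_predicted = drop(predict(object, best)),
    value = value,
    method = method,
    seed = seed,
    maximize = maximize,
    lower = b$lower, upper = b$upper,
    trace = trace
  ), class = "response_optimum")
}

default_bounds <- function(object, lower, upper) {
  ctr <- factor_centers(object$factors)
  stp <- factor_steps(object$factors)
  if (is.null(lower)) lower <- ctr - 2 * stp
  if (is.null(upper)) upper <- ctr + 2 * stp
  if (length(lower) != length(ctr) || length(upper) != length(ctr))
    stop("bounds must have one entry per factor", call. = FALSE)
  list(lower = as.numeric(lower), upper = as.numeric(upper))
}

#' @export
print.response_optimum <- function(x, ...) {
  cat(sprintf("Optimum of %s (%s, %s model)\n", x$response,
              if (x$maximize) "maximized" else "minimized",
              if (x$model_order == 2) "second-order" else "first-order"))
  nm <- names(x$best_natural)
  for (i in seq_along(nm))
    cat(sprintf("  %-12s %8.2f  (coded %+.3f)\n", nm[i],
                x$best_natural[i], x$best_coded[i]))
  cat(sprintf("  best solution %8.2f\n", x$best_predicted))
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Exhaustive lattice search over a box
#'
#' Independent brute-force oracle for the swarm optimizer: evaluates the
#' fitted surface on a regular `n^k` lattice spanning the bounds and returns
#' the exact lattice argmax. Evaluation is vectorized and chunked so a
#' 201^3 lattice runs in seconds; lattices beyond 1e8 points are refused.
#'
#' @param object A fitted `"rsm"` model, or a function of a point.
#' @param lower,upper Natural-unit bounds.
#' @param n Lattice points per dimension (>= 2).
#' @param maximize Direction.
#' @return List with `best_natural`, `best_predicted`, `n`.
#' @export
grid_search <- function(object, lower = NULL, upper = NULL, n = 201,
                        maximize = TRUE) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("'n' must be >= 2", call. = FALSE)
  if (inherits(object, "rsm")) {
    b <- default_bounds(object, lower, upper)
    lower <- b$lower; upper <- b$upper
    evaluate <- function(P) predict(object, P)
  } else {
    stopifnot(is.function(object), !is.null(lower), !is.null(upper))
    lower <- as.numeric(lower); upper <- as.numeric(upper)
    f <- object
    evaluate <- function(P) apply(P, 1, f)
  }
  d <- length(lower)
  if (n^d > 1e8)
    stop("lattice of ", n, "^", d, " points is too large (> 1e8)",
         call. = FALSE)
  axes <- lapply(seq_len(d), function(j)
    seq(lower[j], upper[j], length.out = n))

  # chunk over the last axis to bound memory
  slice <- as.matrix(expand.grid(axes[-d]))
  best_val <- if (maximize) -Inf else Inf
  best_pt <- NULL
  for (v in axes[[d]]) {
    P <- cbind(slice, v)
    z <- evaluate(P)
    i <- if (maximize) which.max(z) else which.min(z)
    if ((maximize && z[i] > best_val) || (!maximize && z[i] < best_val)) {
      best_val <- z[i]
      best_pt <- P[i, ]
    }
  }
  names(best_pt) <- if (inherits(object, "rsm")) names(object$factors)
  list(best_natural = best_pt, best_predicted = best_val, n = n)
}

#' Percent difference between predicted and observed values
#'
#' Validation statistic used when an optimized condition is re-run in the
#' laboratory: `100 * (predicted - experimental) / predicted`, i.e. the
#' deviation as a share of the model's prediction.
#'
#' @param predicted Model prediction (non-zero).
#' @param experimental Measured value.
#' @return Percent difference.
#' @examples
#' percent_difference(7.79, 7.34)
#' @export
percent_difference <- function(predicted, experimental) {
  if (any(predicted == 0))
    stop("percent difference undefined for a zero prediction", call. = FALSE)
  100 * (predicted - experimental) / predicted
}
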