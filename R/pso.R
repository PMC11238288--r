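#' Control parameters for the particle swarm optimizer
#'
#' Defaults follow the configuration used for the fitted-surface
#' optimizations in this package: 50 particles, 50 iterations, cognitive and
#' social coefficients both 0.5, and an inertia weight decayed linearly from
#' 1.0 to 0.1 across the run.
#'
#' @param n_particles Swarm size.
#' @param n_iter Number of iterations (`k_max`).
#' @param c1 Cognitive (personal-best) acceleration coefficient.
#' @param c2 Social (swarm-best) acceleration coefficient.
#' @param w_start,w_end Inertia weight at iteration 0 and at `k_max`;
#'   both must lie in (0, 1].
#' @return A list of class `"pso_control"`.
#' @export
pso_control <- function(n_particles = 50, n_iter = 50, c1 = 0.5, c2 = 0.5,
                        w_start = 1.0, w_end = 0.1) {
  n_particles <- as.integer(n_particles)
  n_iter <- as.integer(n_iter)
  if (is.na(n_particles) || n_particles < 1L)
    stop("'n_particles' must be >= 1", call. = FALSE)
  if (is.na(n_iter) || n_iter < 1L)
    stop("'n_iter' must be >= 1", call. = FALSE)
  if (!is.numeric(c1) || c1 < 0 || !is.numeric(c2) || c2 < 0)
    stop("'c1' and 'c2' must be non-negative", call. = FALSE)
  for (w in c(w_start, w_end))
    if (!is.numeric(w) || w <= 0 || w > 1)
      stop("inertia endpoints must lie in (0, 1]", call. = FALSE)
  structure(list(n_particles = n_particles, n_iter = n_iter, c1 = c1,
                 c2 = c2, w_start = w_start, w_end = w_end),
            class = "pso_control")
}

#' Linearly decaying inertia weight
#'
#' `w(k) = w_start - (w_start - w_end) * k / k_max`: the inertia weight
#' interpolates linearly from `w_start` at iteration 0 to `w_end` at the
#' final iteration.
#'
#' @param k Current iteration, `0 <= k <= k_max`.
#' @param k_max Total number of iterations.
#' @param w_start,w_end Endpoints of the schedule.
#' @return The inertia weight at iteration `k`.
#' @export
inertia_weight <- function(k, k_max, w_start = 1.0, w_end = 0.1) {
  if (any(k < 0) || any(k > k_max))
    stop("'k' must lie in [0, k_max]", call. = FALSE)
  w_start - (w_start - w_end) * k / k_max
}

#' One particle swarm velocity update
#'
#' The canonical velocity rule: retained momentum plus stochastic attraction
#' toward the particle's personal best and the swarm best,
#' `v' = w*v + c1*r1*(pbest - x) + c2*r2*(sbest - x)`.
#' All arguments may be vectors or conformable matrices (particles in rows),
#' so the rule applies one dimension at a time with independent uniform
#' draws `r1`, `r2` per particle per dimension.
#'
#' @param v Current velocity.
#' @param x Current position.
#' @param pbest Personal best position.
#' @param sbest Swarm best position.
#' @param w Inertia weight.
#' @param c1,c2 Acceleration coefficients.
#' @param r1,r2 Uniform(0,1) draws, same shape as `x`.
#' @return The updated velocity.
#' @examples
#' # scalar hand-check: w=0.5, v=1, x=0, pbest=2, sbest=4, r1=r2=0.5
#' pso_velocity(1, 0, 2, 4, 0.5, 0.5, 0.5, 0.5, 0.5)  # 2
#' @export
pso_velocity <- function(v, x, pbest, sbest, w, c1, c2, r1, r2) {
  w * v + c1 * r1 * (pbest - x) + c2 * r2 * (sbest - x)
}

#' Particle swarm optimization over a box
#'
#' Maximizes (or minimizes) a function over bound constraints with a global
#' swarm: positions start uniform in the box with zero velocities; each
#' iteration applies the inertia schedule of [inertia_weight()], the velocity
#' rule of [pso_velocity()] and the position update `x' = x + v'`, clamps any
#' out-of-bound coordinate to the violated bound (zeroing that velocity
#' component), then synchronously refreshes personal bests and the swarm
#' best. Personal bests are replaced only on strict improvement.
#'
#' @param fn Objective taking a numeric vector (one point) and returning a
#'   finite scalar on the box.
#' @param lower,upper Numeric bound vectors, `lower < upper` elementwise.
#' @param control A [pso_control()] list.
#' @param seed Optional integer; makes the run fully reproducible.
#' @param maximize If `FALSE`, minimizes by negating the objective.
#'
#' @return An object of class `"pso"`: `par` (best position), `value` (best
#'   objective on the caller's scale), `trace` (best-so-far value after each
#'   iteration, length `n_iter`, monotone), plus the configuration.
#' @examples
#' sphere <- function(p) -sum((p - c(1, 2))^2)
#' fit <- pso(sphere, lower = c(-5, -5), upper = c(5, 5), seed = 1)
#' fit$par
#' @export
pso <- function(fn, lower, upper, control = pso_control(), seed = NULL,
                maximize = TRUE) {
  stopifnot(is.function(fn), inherits(control, "pso_control"))
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != length(upper) || !length(lower))
    stop("'lower' and 'upper' must be non-empty and of equal length",
         call. = FALSE)
  if (!all(is.finite(lower)) || !all(is.finite(upper)) ||
      any(lower >= upper))
    stop("bounds must be finite with lower < upper", call. = FALSE)
  d <- length(lower)
  np <- control$n_particles
  ni <- control$n_iter
  obj <- if (maximize) fn else function(p) -fn(p)

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }

  warned_nonfinite <- FALSE
  eval_swarm <- function(P) {
    f <- vapply(seq_len(nrow(P)), function(i) obj(P[i, ]), numeric(1))
    bad <- !is.finite(f)
    if (any(bad)) {
      if (!warned_nonfinite) {
        warning("non-finite fitness at ", sum(bad),
                " particle position(s); treated as -Inf", call. = FALSE)
        warned_nonfinite <<- TRUE
      }
      f[bad] <- -Inf
    }
    f
  }

  pos <- sweep(sweep(matrix(stats::runif(np * d), np, d), 2,
                     upper - lower, "*"), 2, lower, "+")
  vel <- matrix(0, np, d)
  fit <- eval_swarm(pos)
  pbest <- pos
  pbest_f <- fit
  g <- which.max(pbest_f)
  sbest <- pbest[g, ]
  sbest_f <- pbest_f[g]

  trace <- numeric(ni)
  for (k in seq_len(ni)) {
    w <- inertia_weight(k, ni, control$w_start, control$w_end)
    r1 <- matrix(stats::runif(np * d), np, d)
    r2 <- matrix(stats::runif(np * d), np, d)
    vel <- pso_velocity(vel, pos, pbest,
                        matrix(sbest, np, d, byrow = TRUE),
                        w, control$c1, control$c2, r1, r2)
    pos <- pos + vel
    for (j in seq_len(d)) {
      lo <- pos[, j] < lower[j]
      pos[lo, j] <- lower[j]; vel[lo, j] <- 0
      hi <- pos[, j] > upper[j]
      pos[hi, j] <- upper[j]; vel[hi, j] <- 0
    }
    fit <- eval_swarm(pos)
    better <- fit > pbest_f
    pbest[better, ] <- pos[better, ]
    pbest_f[better] <- fit[better]
    g <- which.max(pbest_f)
    if (pbest_f[g] > sbest_f) {
      sbest <- pbest[g, ]
      sbest_f <- pbest_f[g]
    }
    trace[k] <- sbest_f
  }

  structure(list(
    par = sbest,
    value = if (maximize) sbest_f else -sbest_f,
    trace = if (maximize) trace else -trace,
    maximize = maximize,
    lower = lower, upper = upper,
    control = control, seed = seed
  ), class = "pso")
}

#' @export
print.pso <- function(x, digits = 4, ...) {
  cat(sprintf("Particle swarm (%d particles x %d iterations, c1=%g c2=%g, w %g->%g)\n",
              x$control$n_particles, x$control$n_iter, x$control$c1,
              x$control$c2, x$control$w_start, x$control$w_end))
  cat("Best value:", format(x$value, digits = digits), "\n")
  cat("At:", paste(format(x$par, digits = digits), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.pso <- function(x, ...) {
  graphics::plot(seq_along(x$trace), x$trace, type = "s",
                 xlab = "iteration", ylab = "best fitness",
                 main = "Swarm convergence", ...)
  invisible(x)
}
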