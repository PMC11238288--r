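#' Generate a CCD response table from a known surface
#'
#' Synthetic-data generator with known ground truth: builds the central
#' composite design for the supplied factors and draws each run's response
#' as the coded-basis polynomial at the design point plus i.i.d. Gaussian
#' noise. The generator mirrors the assumptions of the OLS/ANOVA analysis —
#' a quadratic (or affine) mean surface, homoscedastic errors on run means,
#' replication only at the centre — so the fitter and generator form a
#' consistent pair for parameter-recovery studies.
#'
#' @param beta Coefficient vector in the fixed coded basis
#'   `[1, x1..xk, x1^2..xk^2, pairwise interactions]` for a second-order
#'   truth, or `[1, x1..xk]` for a first-order truth.
#' @param factors List of [ccd_factor()] objects.
#' @param noise_sd Standard deviation of the added Gaussian noise (>= 0).
#' @param alpha,n_center Design geometry, as in [ccd_design()].
#' @param seed Optional integer seed; the RNG state is restored on exit.
#' @param response Name for the response column.
#' @return Data frame with `run`, the natural-unit factor columns and the
#'   response — the same schema as the packaged experiment table, directly
#'   consumable by [rsm()].
#' @examples
#' truth <- c(7.5, -0.5, -0.2, 0.05, -0.3, -0.35, -0.04, 0.08, 0.23, 0.59)
#' tab <- simulate_ccd_response(truth, parsley_factors(), noise_sd = 0.1,
#'                              seed = 1)
#' fit <- rsm(y ~ time + amplitude + temperature, tab, parsley_factors())
#' @export
simulate_ccd_response <- function(beta, factors, noise_sd = 0, alpha = 2,
                                  n_center = 6, seed = NULL, response = "y") {
  factors <- check_factors(factors)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("'noise_sd' must be >= 0", call. = FALSE)
  k <- length(factors)
  p1 <- 1 + k
  p2 <- 1 + 2 * k + choose(k, 2)
  order <- if (length(beta) == p2) 2L else if (length(beta) == p1) 1L else
    stop("'beta' must have length ", p1, " (first-order) or ", p2,
         " (second-order) for ", k, " factors", call. = FALSE)

  des <- ccd_design(factors, alpha = alpha, n_center = n_center)
  X <- rsm_model_matrix(coded_matrix(des), order)
  mu <- drop(X %*% beta)

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  y <- mu + stats::rnorm(length(mu), 0, noise_sd)

  out <- des$points[c("run", names(factors))]
  out[[response]] <- y
  out
}

#' Monte-Carlo parameter recovery for the CCD fitter
#'
#' Repeats simulate-then-fit under a known coded-basis truth and aggregates,
#' per coefficient: the mean estimate, bias, root-mean-square error, and
#' coverage of the nominal 95% t-intervals built from each fit's coefficient
#' standard errors.
#'
#' @param beta True coefficient vector (see [simulate_ccd_response()]).
#' @param factors List of [ccd_factor()] objects.
#' @param noise_sd Noise standard deviation of the generator.
#' @param n_reps Number of replicate datasets (>= 10).
#' @param seed Integer seed for the whole experiment.
#' @param level Interval confidence level.
#' @param alpha,n_center Design geometry.
#' @return Data frame with one row per coefficient: `term`, `truth`,
#'   `mean_est`, `bias`, `rmse`, `coverage`.
#' @export
recovery_experiment <- function(beta, factors, noise_sd, n_reps, seed = NULL,
                                level = 0.95, alpha = 2, n_center = 6) {
  factors <- check_factors(factors)
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 10L)
    stop("'n_reps' must be at least 10", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }

  fml <- stats::as.formula(paste("y ~", paste(names(factors), collapse = "+")))
  k <- length(factors)
  order <- if (length(beta) == 1 + k) 1L else 2L

  est <- se <- NULL
  for (r in seq_len(n_reps)) {
    tab <- simulate_ccd_response(beta, factors, noise_sd = noise_sd,
                                 alpha = alpha, n_center = n_center)
    fit <- rsm(fml, tab, factors, order = order)
    est <- rbind(est, coef(fit))
    se <- rbind(se, sqrt(diag(fit$cov.unscaled)) * fit$sigma)
    df_res <- fit$df.residual
  }
  tcrit <- stats::qt(1 - (1 - level) / 2, df_res)
  truth <- matrix(beta, n_reps, length(beta), byrow = TRUE)
  covered <- abs(est - truth) <= tcrit * se

  data.frame(
    term = colnames(est),
    truth = beta,
    mean_est = colMeans(est),
    bias = colMeans(est) - beta,
    rmse = sqrt(colMeans((est - truth)^2)),
    coverage = colMeans(covered),
    row.names = NULL
  )
}
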