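#' Fit a response-surface model by ordinary least squares in coded units
#'
#' Fits either the full second-order polynomial
#' \deqn{y = b_0 + \sum_i b_i x_i + \sum_i b_{ii} x_i^2 + \sum_{i<j} b_{ij} x_i x_j + \epsilon}
#' or the first-order multiple-linear-regression model
#' \deqn{y = \beta_0 + \sum_i \beta_i x_i + \epsilon}
#' to run means from a designed experiment. All fitting happens on the coded
#' scale `x = (natural - center)/step`; the adjusted sums of squares of the
#' usual response-surface ANOVA are only reproducible in that basis.
#' Predictions accept natural-unit points and are coded internally.
#'
#' @param formula Model variables, e.g.
#'   `chlorophyll ~ time + amplitude + temperature`. The right-hand side
#'   names the factor columns of `data`; the polynomial degree is set by
#'   `order`, not by the formula.
#' @param data Data frame with one row per run, holding the response and the
#'   natural-unit factor columns.
#' @param factors List of [ccd_factor()] objects covering every right-hand
#'   side variable (extra entries are ignored).
#' @param order 1 for the first-order (MLR) model, 2 for the full quadratic
#'   (RSM) model.
#'
#' @return An object of class `"rsm"` with components `coefficients`
#'   (coded-basis), `fitted.values`, `residuals`, `df.residual`, `sigma`,
#'   `model_matrix`, `coded`, `hat`, `cov.unscaled` and the fitting metadata.
#'   Supports `print()`, `summary()`, `coef()`, `predict()`, `fitted()`,
#'   `residuals()`, `anova()`, `plot()` and `simulate()`.
#' @examples
#' pj <- parsley_juice()
#' fit <- rsm(chlorophyll ~ time + amplitude + temperature,
#'            data = pj, factors = parsley_factors())
#' coef(fit)
#' predict(fit, c(time = 4.4, amplitude = 88.69, temperature = 60))
#' @export
rsm <- function(formula, data, factors, order = 2) {
  stopifnot(inherits(formula, "formula"), length(formula) == 3L)
  order <- as.integer(order)
  if (!order %in% 1:2) stop("'order' must be 1 or 2", call. = FALSE)
  factors <- check_factors(factors)

  response <- deparse(formula[[2]])
  rhs <- all.vars(formula[[3]])
  missing_fac <- setdiff(rhs, names(factors))
  if (length(missing_fac))
    stop("no ccd_factor supplied for: ", paste(missing_fac, collapse = ", "),
         call. = FALSE)
  missing_col <- setdiff(c(response, rhs), names(data))
  if (length(missing_col))
    stop("column(s) missing from 'data': ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  factors <- factors[rhs]

  y <- as.numeric(data[[response]])
  if (anyNA(y) || !all(is.finite(y)))
    stop("response contains missing or non-finite values", call. = FALSE)
  natural <- as.matrix(data[rhs])
  coded <- to_coded(natural, factors)
  X <- rsm_model_matrix(coded, order)

  n <- nrow(X); p <- ncol(X)
  if (n <= p)
    stop("need more runs (", n, ") than model terms (", p, ")", call. = FALSE)
  fit <- stats::lm.fit(X, y)
  if (fit$rank < p)
    stop("singular fit: design matrix has rank ", fit$rank, " < ", p,
         call. = FALSE)

  qrX <- qr(X)
  Q <- qr.Q(qrX)
  hat <- rowSums(Q^2)
  R <- qr.R(qrX)
  cov_unscaled <- chol2inv(R)
  dimnames(cov_unscaled) <- list(colnames(X), colnames(X))

  res <- y - drop(X %*% fit$coefficients)
  df_res <- n - p
  sigma2 <- sum(res^2) / df_res

  structure(list(
    coefficients = fit$coefficients,
    fitted.values = drop(X %*% fit$coefficients),
    residuals = res,
    df.residual = df_res,
    sigma = sqrt(sigma2),
    model_matrix = X,
    coded = coded,
    y = y,
    response = response,
    factors = factors,
    order = order,
    hat = hat,
    cov.unscaled = cov_unscaled,
    coded_range = range(coded),
    call = match.call()
  ), class = "rsm")
}

# Fixed column basis: [1, x1..xk, x1^2..xk^2, x1:x2, x1:x3, ..., x(k-1):xk]
rsm_model_matrix <- function(coded, order) {
  coded <- as.matrix(coded)
  k <- ncol(coded)
  nm <- colnames(coded)
  if (is.null(nm)) nm <- paste0("x", seq_len(k))
  X <- cbind(`(Intercept)` = 1, coded)
  colnames(X)[-1] <- nm
  if (order == 2) {
    sq <- coded^2
    colnames(sq) <- paste0(nm, "^2")
    ia <- NULL
    if (k >= 2) {
      pairs <- utils::combn(k, 2)
      ia <- apply(pairs, 2, function(ij) coded[, ij[1]] * coded[, ij[2]])
      ia <- matrix(ia, nrow = nrow(coded))
      colnames(ia) <- apply(pairs, 2, function(ij)
        paste(nm[ij[1]], nm[ij[2]], sep = ":"))
    }
    X <- cbind(X, sq, ia)
  }
  X
}

#' @export
print.rsm <- function(x, digits = 4, ...) {
  kind <- if (x$order == 2) "Second-order response surface"
          else "First-order (multiple linear regression) model"
  cat(kind, "fitted in coded units\n")
  cat("Response:", x$response, "  runs:", length(x$y), "\n\n")
  cat("Coefficients (coded basis):\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.rsm <- function(object, ...) object$coefficients

#' @export
fitted.rsm <- function(object, ...) object$fitted.values

#' @export
residuals.rsm <- function(object, ...) object$residuals

#' Predict from a fitted response surface
#'
#' @param object A fitted `"rsm"` model.
#' @param newdata Natural-unit query points: a numeric vector (one value per
#'   factor, in model order), a matrix, or a data frame with the factor
#'   columns. Missing `newdata` returns the in-sample fitted values.
#' @param coded Set `TRUE` if `newdata` is already on the coded scale.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.rsm <- function(object, newdata, coded = FALSE, ...) {
  if (missing(newdata) || is.null(newdata)) return(object$fitted.values)
  k <- length(object$factors)
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata[names(object$factors)])
  if (!is.matrix(newdata)) newdata <- matrix(as.numeric(newdata), ncol = k,
                                             byrow = TRUE)
  cd <- if (coded) newdata else to_coded(newdata, object$factors)
  lim <- max(abs(object$coded_range))
  if (any(abs(cd) > lim + 1e-8))
    warning("predicting outside the fitted design region (|coded| > ",
            format(lim), ")", call. = FALSE)
  colnames(cd) <- names(object$factors)
  X <- rsm_model_matrix(cd, object$order)
  drop(X %*% object$coefficients)
}

#' Leave-one-out prediction error sum of squares
#'
#' PRESS via the leverage identity: `sum((e_i / (1 - h_ii))^2)` with
#' `e_i` the ordinary residuals and `h_ii` the hat-matrix diagonal.
#'
#' @param object A fitted `"rsm"` model.
#' @return The PRESS statistic.
#' @export
press <- function(object) {
  stopifnot(inherits(object, "rsm"))
  sum((object$residuals / (1 - object$hat))^2)
}

#' @export
summary.rsm <- function(object, ...) {
  se <- sqrt(diag(object$cov.unscaled)) * object$sigma
  tval <- object$coefficients / se
  pval <- 2 * stats::pt(abs(tval), object$df.residual, lower.tail = FALSE)
  coef_table <- cbind(Estimate = object$coefficients, `Std. Error` = se,
                      `t value` = tval, `Pr(>|t|)` = pval)
  sst <- sum((object$y - mean(object$y))^2)
  sse <- sum(object$residuals^2)
  n <- length(object$y)
  r2 <- 1 - sse / sst
  adj_r2 <- 1 - (sse / object$df.residual) / (sst / (n - 1))
  pred_r2 <- 1 - press(object) / sst
  p_model <- n - 1 - object$df.residual
  f_model <- ((sst - sse) / p_model) / (sse / object$df.residual)
  structure(list(
    call = object$call, response = object$response, order = object$order,
    coefficients = coef_table, sigma = object$sigma,
    df = c(p_model, object$df.residual),
    r.squared = r2, adj.r.squared = adj_r2, pred.r.squared = pred_r2,
    fstatistic = c(value = f_model, numdf = p_model,
                   dendf = object$df.residual)
  ), class = "summary.rsm")
}

#' @export
print.summary.rsm <- function(x, digits = 4, ...) {
  cat("Response:", x$response,
      if (x$order == 2) "(second-order RSM)" else "(first-order MLR)", "\n\n")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat(sprintf("\nResidual standard error: %.4g on %d degrees of freedom\n",
              x$sigma, x$df[2]))
  cat(sprintf("R-squared: %.2f%%   adjusted: %.2f%%   predicted (PRESS): %.2f%%\n",
              100 * x$r.squared, 100 * x$adj.r.squared,
              100 * x$pred.r.squared))
  cat(sprintf("Model F = %.2f on %d and %d df, p = %.3g\n",
              x$fstatistic["value"], x$fstatistic["numdf"],
              x$fstatistic["dendf"],
              stats::pf(x$fstatistic["value"], x$fstatistic["numdf"],
                        x$fstatistic["dendf"], lower.tail = FALSE)))
  invisible(x)
}

#' Contour view of a fitted surface
#'
#' Draws a filled contour of the predicted response over two factors with the
#' remaining factors held at their centres — a 2-D cut through the surfaces
#' usually shown as 3-D response plots.
#'
#' @param x A fitted `"rsm"` model.
#' @param vary Character vector of two factor names to vary.
#' @param n Grid points per axis.
#' @param ... Passed to [graphics::filled.contour()].
#' @export
plot.rsm <- function(x, vary = names(x$factors)[1:2], n = 60, ...) {
  stopifnot(length(vary) == 2L, all(vary %in% names(x$factors)))
  lim <- max(abs(x$coded_range))
  grids <- lapply(x$factors[vary], function(f)
    seq(f$center - lim * f$step, f$center + lim * f$step, length.out = n))
  pts <- as.matrix(expand.grid(grids))
  full <- matrix(rep(factor_centers(x$factors), each = nrow(pts)),
                 ncol = length(x$factors),
                 dimnames = list(NULL, names(x$factors)))
  full[, vary] <- pts
  z <- matrix(predict(x, full), n, n)
  graphics::filled.contour(
    grids[[1]], grids[[2]], z,
    color.palette = grDevices::hcl.colors,
    xlab = vary[1], ylab = vary[2],
    main = paste("Predicted", x$response), ...)
  invisible(x)
}

#' Simulate responses from a fitted surface
#'
#' Draws new response vectors at the model's own design points:
#' fitted values plus i.i.d. Gaussian noise.
#'
#' @param object A fitted `"rsm"` model.
#' @param nsim Number of response vectors.
#' @param seed Optional integer seed (restores the RNG state on exit).
#' @param noise_sd Noise standard deviation; defaults to the residual sigma.
#' @param ... Unused.
#' @return Data frame with `nsim` columns of simulated responses.
#' @export
simulate.rsm <- function(object, nsim = 1, seed = NULL, noise_sd = object$sigma,
                         ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  n <- length(object$fitted.values)
  out <- as.data.frame(replicate(
    nsim, object$fitted.values + stats::rnorm(n, 0, noise_sd), simplify = FALSE),
    col.names = paste0("sim_", seq_len(nsim)))
  out
}
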