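#' Define a process factor for coded-unit design work
#'
#' A factor is stored by its centre and step so that any real-valued query
#' point (for example a validation condition such as 4.4 min) has a coded
#' image, not just the five design levels. Coded value `0` is the centre;
#' one coded unit equals one `step` in natural units.
#'
#' @param name Variable name, used to match data columns and model formulas.
#' @param center Natural-unit value at coded 0.
#' @param step Natural units per coded unit; must be strictly positive.
#' @param unit Optional unit label used in printing (e.g. `"min"`).
#'
#' @return An object of class `"ccd_factor"`.
#' @seealso [ccd_design()], [to_coded()], [to_natural()]
#' @examples
#' time <- ccd_factor("time", center = 8, step = 2, unit = "min")
#' to_coded(c(time = 4), list(time))
#' @export
ccd_factor <- function(name, center, step, unit = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  center <- as.numeric(center)
  step <- as.numeric(step)
  if (length(center) != 1L || !is.finite(center))
    stop("'center' must be a single finite number", call. = FALSE)
  if (length(step) != 1L || !is.finite(step) || step <= 0)
    stop("'step' must be a single positive number (factor '", name, "')",
         call. = FALSE)
  structure(list(name = name, center = center, step = step, unit = unit),
            class = "ccd_factor")
}

#' @export
print.ccd_factor <- function(x, ...) {
  cat(sprintf("Factor %s: center %g, step %g %s\n",
              x$name, x$center, x$step, x$unit))
  invisible(x)
}

#' The three thermosonication process factors
#'
#' Sonication time (centre 8 min, step 2), ultrasound amplitude (centre 80%,
#' step 10) and treatment temperature (centre 50 degC, step 5) — the factor
#' coding used throughout the packaged parsley-juice experiment, whose five
#' design levels span 4–12 min, 60–100% and 40–60 degC.
#'
#' @return A named list of three [ccd_factor()] objects.
#' @examples
#' parsley_factors()
#' @export
parsley_factors <- function() {
  list(
    time        = ccd_factor("time", 8, 2, "min"),
    amplitude   = ccd_factor("amplitude", 80, 10, "%"),
    temperature = ccd_factor("temperature", 50, 5, "degC")
  )
}

check_factors <- function(factors) {
  if (inherits(factors, "ccd_factor")) factors <- list(factors)
  if (!is.list(factors) || !length(factors) ||
      !all(vapply(factors, inherits, logical(1), "ccd_factor")))
    stop("'factors' must be a list of ccd_factor objects", call. = FALSE)
  names(factors) <- vapply(factors, `[[`, character(1), "name")
  factors
}

factor_centers <- function(factors) vapply(factors, `[[`, numeric(1), "center")
factor_steps <- function(factors) vapply(factors, `[[`, numeric(1), "step")

#' Convert between natural and coded units
#'
#' `to_coded()` maps natural-unit values to the coded scale,
#' `coded = (natural - center) / step`; `to_natural()` is its exact inverse.
#' Both accept a numeric vector (one value per factor) or a matrix /
#' data frame with one column per factor.
#'
#' @param x Numeric vector, matrix or data frame of factor values.
#' @param factors List of [ccd_factor()] objects, in column order.
#' @return An object of the same shape as `x` on the other scale.
#' @examples
#' fac <- parsley_factors()
#' to_coded(c(4.4, 88.69, 60), fac)
#' to_natural(c(-2, 0, 0), fac)
#' @export
to_coded <- function(x, factors) {
  factors <- check_factors(factors)
  transform_units(x, factors, function(v, ctr, stp) (v - ctr) / stp)
}

#' @rdname to_coded
#' @export
to_natural <- function(x, factors) {
  factors <- check_factors(factors)
  transform_units(x, factors, function(v, ctr, stp) ctr + stp * v)
}

transform_units <- function(x, factors, f) {
  ctr <- factor_centers(factors)
  stp <- factor_steps(factors)
  k <- length(factors)
  if (is.data.frame(x)) x <- as.matrix(x[names(factors)])
  if (is.matrix(x)) {
    if (ncol(x) != k)
      stop("expected ", k, " columns, got ", ncol(x), call. = FALSE)
    out <- x
    for (j in seq_len(k)) out[, j] <- f(x[, j], ctr[j], stp[j])
    colnames(out) <- names(factors)
    return(out)
  }
  if (length(x) != k)
    stop("expected ", k, " values, got ", length(x), call. = FALSE)
  out <- f(as.numeric(x), ctr, stp)
  names(out) <- names(factors)
  out
}
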