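#' Model-adequacy metrics for paired experimental / predicted values
#'
#' The three statistics conventionally used to compare response-surface and
#' multiple-regression fits of the same data:
#'
#' * `r_squared()` — coefficient of determination,
#'   `1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)`.
#' * `rmse()` — root-mean-square error with denominator `n` (not `n - p`),
#'   `sqrt(mean((pred - obs)^2))`.
#' * `aad()` — absolute average deviation in percent,
#'   `100 * mean(abs(pred - obs) / abs(obs))`.
#'
#' @param observed Numeric vector of experimental values.
#' @param predicted Numeric vector of model predictions, same length.
#' @return A single number.
#' @examples
#' obs <- c(100, 100); pred <- c(90, 110)
#' aad(obs, pred)    # 10
#' rmse(obs, pred)   # 10
#' @name adequacy_metrics
NULL

check_pairs <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("'observed' and 'predicted' must have equal length", call. = FALSE)
  if (length(observed) < 1L) stop("empty input", call. = FALSE)
  if (!all(is.finite(observed)) || !all(is.finite(predicted)))
    stop("inputs must be finite", call. = FALSE)
}

#' @rdname adequacy_metrics
#' @export
r_squared <- function(observed, predicted) {
  check_pairs(observed, predicted)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0)
    stop("R-squared undefined: observed values have zero variance",
         call. = FALSE)
  1 - sum((observed - predicted)^2) / sst
}

#' @rdname adequacy_metrics
#' @export
rmse <- function(observed, predicted) {
  check_pairs(observed, predicted)
  sqrt(mean((predicted - observed)^2))
}

#' @rdname adequacy_metrics
#' @export
aad <- function(observed, predicted) {
  check_pairs(observed, predicted)
  zero <- which(observed == 0)
  if (length(zero))
    stop("AAD undefined: observed value is zero at position ",
         paste(zero, collapse = ", "), call. = FALSE)
  100 * mean(abs(predicted - observed) / abs(observed))
}

#' Adequacy metrics of a fitted surface
#'
#' Convenience wrapper returning the in-sample R-squared, RMSE and AAD of an
#' `"rsm"` fit against its own training response.
#'
#' @param object A fitted `"rsm"` model.
#' @return Named numeric vector `c(r_squared, rmse, aad_pct)`.
#' @export
model_metrics <- function(object) {
  stopifnot(inherits(object, "rsm"))
  obs <- object$y
  pred <- object$fitted.values
  c(r_squared = r_squared(obs, pred),
    rmse = rmse(obs, pred),
    aad_pct = aad(obs, pred))
}
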