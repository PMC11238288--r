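#' Build a central composite design
#'
#' Constructs the standard rotatable-style CCD for `k` factors: the full
#' 2^k factorial cube (levels -1/+1, Yates order), 2k axial (star) points at
#' distance `alpha` on each axis, and `n_center` replicated centre runs.
#' Natural-unit coordinates follow each factor's centre/step coding. For the
#' three-factor design used here with `alpha = 2` and six centre runs the
#' layout has 20 runs and its coded columns are mutually orthogonal with
#' moments sum(x_i^2) = 16, sum(x_i^4) = 40 and sum(x_i^2 x_j^2) = 8.
#'
#' @param factors List of [ccd_factor()] objects (one per dimension).
#' @param alpha Axial distance in coded units; default 2.
#' @param n_center Number of centre replicates; default 6.
#'
#' @return An object of class `"ccd_design"`: a list with `factors`, `alpha`,
#'   and `points`, a data frame holding `run`, `point_class`, the coded
#'   columns and the natural-unit columns (named after the factors).
#' @examples
#' des <- ccd_design(parsley_factors())
#' table(des$points$point_class)
#' colSums(coded_matrix(des))
#' @export
ccd_design <- function(factors, alpha = 2, n_center = 6) {
  factors <- check_factors(factors)
  k <- length(factors)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0)
    stop("'alpha' must be a single positive number", call. = FALSE)
  n_center <- as.integer(n_center)
  if (is.na(n_center) || n_center < 1L)
    stop("'n_center' must be a positive integer", call. = FALSE)

  # factorial cube in Yates order: first factor alternates fastest
  cube <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  axial <- matrix(0, 2L * k, k)
  for (j in seq_len(k)) {
    axial[2L * j - 1L, j] <- -alpha
    axial[2L * j, j] <- alpha
  }
  centre <- matrix(0, n_center, k)
  coded <- rbind(cube, axial, centre)
  dimnames(coded) <- list(NULL, names(factors))

  cls <- rep(c("factorial", "axial", "center"),
             c(nrow(cube), nrow(axial), n_center))
  natural <- to_natural(coded, factors)
  pts <- data.frame(run = seq_len(nrow(coded)), point_class = cls)
  for (j in seq_len(k)) pts[[names(factors)[j]]] <- natural[, j]
  structure(list(factors = factors, alpha = alpha, n_center = n_center,
                 points = pts, coded = coded),
            class = "ccd_design")
}

#' Coded design matrix of a CCD
#'
#' @param design A `"ccd_design"` object.
#' @return Numeric matrix of coded factor levels, one row per run.
#' @export
coded_matrix <- function(design) {
  stopifnot(inherits(design, "ccd_design"))
  design$coded
}

#' @export
print.ccd_design <- function(x, ...) {
  k <- length(x$factors)
  cat(sprintf("Central composite design: %d factors, %d runs\n",
              k, nrow(x$points)))
  cat(sprintf("  %d factorial + %d axial (alpha = %g) + %d center\n",
              2^k, 2 * k, x$alpha, x$n_center))
  for (f in x$factors)
    cat(sprintf("  %-12s center %g step %g %s\n",
                f$name, f$center, f$step, f$unit))
  invisible(x)
}

#' @export
as.data.frame.ccd_design <- function(x, ...) {
  out <- x$points
  cd <- x$coded
  colnames(cd) <- paste0("coded_", colnames(cd))
  cbind(out, as.data.frame(cd))
}
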