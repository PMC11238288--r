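#' The thermosonicated parsley-juice experiment
#'
#' The packaged 20-run central composite experiment: sonication time,
#' ultrasound amplitude and temperature against two responses, total
#' chlorophyll (mg/100 mL) and ascorbic acid (mg/100 g), each a mean of
#' triplicate assays with its replicate standard deviation. The
#' `*_rsm`/`*_mlr` columns carry the predictions reported alongside the
#' original experiment, retained for cross-checking refits.
#'
#' `parsley_validation()` returns the independently measured confirmation
#' condition (4.4 min, 88.69%, 60 degC): the surface predictions reported
#' for it and the experimental values from the confirmation runs.
#'
#' @return `parsley_juice()`: the 20-run data frame. `parsley_validation()`:
#'   a one-row data frame with the confirmation point, predictions and
#'   measurements.
#' @examples
#' pj <- parsley_juice()
#' nrow(pj)
#' @export
parsley_juice <- function() {
  path <- system.file("extdata", "parsley_juice_ccd.csv", package = "rsmpso",
                      mustWork = TRUE)
  read_response_table(path, parsley_factors(),
                      responses = c("chlorophyll", "ascorbic_acid"))
}

#' @rdname parsley_juice
#' @export
parsley_validation <- function() {
  data.frame(
    time = 4.4, amplitude = 88.69, temperature = 60,
    chlorophyll_pred = 7.79, chlorophyll_exp = 7.34,
    ascorbic_acid_pred = 145.42, ascorbic_acid_exp = 139.23
  )
}

#' Read and validate a CCD response table
#'
#' Reads a run-per-row CSV, checks that every factor column and requested
#' response column is present, numeric and finite, and that run identifiers
#' are unique. Coded units are always recomputed from the natural columns
#' and the supplied factor definitions — any coded columns in the file are
#' ignored, so the coding convention cannot drift from the file.
#'
#' @param path CSV file with a header; must contain a `run` column, one
#'   column per factor (matching the factor names) and the response columns.
#' @param factors List of [ccd_factor()] objects.
#' @param responses Character vector of response column names to validate.
#' @return The validated data frame, with a `"coded"` attribute holding the
#'   recomputed coded matrix.
#' @export
read_response_table <- function(path, factors, responses) {
  factors <- check_factors(factors)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("run", names(factors), responses)
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("missing column(s) in ", basename(path), ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$run))
    stop("duplicate run id(s): ",
         paste(unique(tab$run[duplicated(tab$run)]), collapse = ", "),
         call. = FALSE)
  for (cl in c(names(factors), responses)) {
    v <- tab[[cl]]
    if (!is.numeric(v) || !all(is.finite(v))) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))
      stop("non-numeric or non-finite value in column '", cl, "' (row ",
           paste(bad, collapse = ", "), ")", call. = FALSE)
    }
  }
  attr(tab, "coded") <- to_coded(as.matrix(tab[names(factors)]), factors)
  tab
}

#' Write an analysis report to JSON (with a plain-text sidecar)
#'
#' Serializes ANOVA tables, fitted surfaces, optimization results or metric
#' vectors as JSON at full precision, and writes the corresponding aligned
#' human-readable rendering next to it (same path with extension `.txt`).
#'
#' @param x An `"rsm"`, `"rsm_anova"`, `"response_optimum"` object, or any
#'   list/vector of results.
#' @param path Output file path ending in `.json`.
#' @param text Also write the `.txt` rendering (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, text = TRUE) {
  payload <- report_payload(x)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (text) {
    txt <- sub("\\.json$", ".txt", path)
    if (identical(txt, path)) txt <- paste0(path, ".txt")
    writeLines(utils::capture.output(print(x)), txt)
  }
  invisible(path)
}

report_payload <- function(x) {
  if (inherits(x, "rsm")) {
    list(kind = "fitted_surface",
         response = x$response,
         order = x$order,
         basis = "coded",
         coefficients = as.list(coef(x)),
         sigma = x$sigma,
         factors = lapply(x$factors, function(f)
           list(name = f$name, center = f$center, step = f$step,
                unit = f$unit)))
  } else if (inherits(x, "rsm_anova")) {
    list(kind = "anova",
         response = attr(x, "response"),
         rows = as.data.frame(x),
         r_squared = attr(x, "r.squared"),
         adj_r_squared = attr(x, "adj.r.squared"),
         pred_r_squared = attr(x, "pred.r.squared"))
  } else if (inherits(x, "response_optimum")) {
    list(kind = "optimum",
         response = x$response,
         model_order = x$model_order,
         method = x$method,
         seed = x$seed,
         best_natural = as.list(x$best_natural),
         best_coded = as.list(x$best_coded),
         best_predicted = x$best_predicted,
         lower = x$lower, upper = x$upper)
  } else {
    x
  }
}

#' Prediction grid for external surface plotting
#'
#' Evaluates a fitted surface on a regular two-factor grid (remaining
#' factors at their centres) and returns it in long form, ready to be
#' written as CSV for 3-D plotting elsewhere.
#'
#' @param object A fitted `"rsm"` model.
#' @param vary Two factor names to vary.
#' @param n Grid points per axis.
#' @param span Half-width of the grid in coded units (default 2, the design
#'   region).
#' @return Data frame with the two varied factor columns and `predicted`.
#' @export
prediction_grid <- function(object, vary = names(object$factors)[1:2],
                            n = 50, span = 2) {
  stopifnot(inherits(object, "rsm"), length(vary) == 2L,
            all(vary %in% names(object$factors)))
  grids <- lapply(object$factors[vary], function(f)
    seq(f$center - span * f$step, f$center + span * f$step, length.out = n))
  pts <- expand.grid(grids)
  full <- as.data.frame(matrix(rep(factor_centers(object$factors),
                                   each = nrow(pts)),
                               ncol = length(object$factors),
                               dimnames = list(NULL, names(object$factors))))
  full[vary] <- pts
  full$predicted <- predict(object, full)
  full
}
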