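#' Spectrophotometric chlorophyll determination
#'
#' Pigment content from absorbances of an 80% acetone extract at 645 and
#' 663 nm, using the Hiscox–Israelstam / Arnon coefficient set by default:
#' \deqn{chl_a = 12.7 A_{663} - 2.69 A_{645}}
#' \deqn{chl_b = 22.9 A_{645} - 4.68 A_{663}}
#' \deqn{chl_{total} = 20.2 A_{645} + 8.02 A_{663}}
#' all in mg/L of extract; `total_chlorophyll()` converts to mg per 100 mL
#' and applies the dilution factor. The coefficient set is overridable for
#' other solvent systems. A computed pigment below zero (possible with noisy
#' absorbances) is clipped to zero with a warning.
#'
#' @param a645,a663 Absorbances at 645 and 663 nm (non-negative).
#' @param dilution Dilution factor of the extract.
#' @param coefficients Coefficient set from [chlorophyll_coefficients()].
#' @return `total_chlorophyll()`: total chlorophyll in mg/100 mL.
#'   `chlorophyll_ab()`: named vector with `chl_a`, `chl_b`, `total`
#'   in mg/L.
#' @examples
#' total_chlorophyll(a645 = 0.5, a663 = 0.5)  # 1.411 mg/100 mL
#' @export
total_chlorophyll <- function(a645, a663, dilution = 1,
                              coefficients = chlorophyll_coefficients()) {
  check_absorbance(a645, "a645"); check_absorbance(a663, "a663")
  if (any(dilution <= 0)) stop("'dilution' must be positive", call. = FALSE)
  mg_l <- unname(coefficients$total[1] * a645 + coefficients$total[2] * a663)
  mg_l / 10 * dilution
}

#' @rdname total_chlorophyll
#' @export
chlorophyll_ab <- function(a645, a663,
                           coefficients = chlorophyll_coefficients()) {
  check_absorbance(a645, "a645"); check_absorbance(a663, "a663")
  chl_a <- unname(coefficients$a[1] * a663 - coefficients$a[2] * a645)
  chl_b <- unname(coefficients$b[1] * a645 - coefficients$b[2] * a663)
  if (any(c(chl_a, chl_b) < 0)) {
    warning("negative computed pigment clipped to 0", call. = FALSE)
    chl_a <- pmax(chl_a, 0); chl_b <- pmax(chl_b, 0)
  }
  c(chl_a = chl_a, chl_b = chl_b,
    total = unname(coefficients$total[1] * a645 +
                     coefficients$total[2] * a663))
}

#' @rdname total_chlorophyll
#' @export
chlorophyll_coefficients <- function() {
  list(a = c(A663 = 12.7, A645 = 2.69),
       b = c(A645 = 22.9, A663 = 4.68),
       total = c(A645 = 20.2, A663 = 8.02))
}

check_absorbance <- function(a, name) {
  if (!all(is.finite(a)) || any(a < 0))
    stop("'", name, "' must be finite and non-negative", call. = FALSE)
}

#' Ascorbic acid by DCPIP titration
#'
#' Mass of ascorbic acid from a 2,6-dichloroindophenol (DCPIP) titration:
#' `molar_mass * c_dcpip * v_dcpip` grams reduced at the endpoint, scaled by
#' the sample volume to a concentration basis — mg per 100 mL by default, or
#' mg per 100 g when the titrated sample mass is supplied.
#'
#' @param v_dcpip Titrant volume at the endpoint, in litres.
#' @param c_dcpip Titrant molar concentration, mol/L.
#' @param v_sample Titrated sample volume, in litres (> 0).
#' @param molar_mass Molar mass of ascorbic acid, g/mol (default 176.12).
#' @param basis `"per_100_ml"` or `"per_100_g"`.
#' @param sample_mass_g Mass of sample titrated, required for the
#'   `"per_100_g"` basis.
#' @return Ascorbic acid in mg per 100 mL (or mg per 100 g).
#' @examples
#' # 5 mL of 1 mM DCPIP against 10 mL of juice
#' ascorbic_acid_titration(v_dcpip = 0.005, c_dcpip = 0.001, v_sample = 0.010)
#' @export
ascorbic_acid_titration <- function(v_dcpip, c_dcpip, v_sample,
                                    molar_mass = 176.12,
                                    basis = c("per_100_ml", "per_100_g"),
                                    sample_mass_g = NULL) {
  basis <- match.arg(basis)
  if (any(v_dcpip < 0)) stop("'v_dcpip' must be >= 0", call. = FALSE)
  if (any(c_dcpip <= 0) || any(molar_mass <= 0))
    stop("'c_dcpip' and 'molar_mass' must be positive", call. = FALSE)
  if (any(v_sample <= 0)) stop("'v_sample' must be positive", call. = FALSE)
  mg <- molar_mass * c_dcpip * v_dcpip * 1000
  if (basis == "per_100_ml") {
    mg / (v_sample * 1000) * 100
  } else {
    if (is.null(sample_mass_g) || any(sample_mass_g <= 0))
      stop("'sample_mass_g' must be supplied (positive) for the per-100-g basis",
           call. = FALSE)
    mg / sample_mass_g * 100
  }
}

#' DPPH radical scavenging activity
#'
#' Percent inhibition of the 2,2-diphenyl-1-picrylhydrazyl radical:
#' `100 * (A0 - A1) / A0` with `A0` the control absorbance and `A1` the
#' sample absorbance at 517 nm.
#'
#' @param a_control Absorbance of the DPPH control (> 0).
#' @param a_sample Absorbance of the sample (>= 0).
#' @return Percent inhibition.
#' @examples
#' dpph_inhibition(0.8, 0.2824)  # 64.7
#' @export
dpph_inhibition <- function(a_control, a_sample) {
  if (any(a_control <= 0)) stop("'a_control' must be positive", call. = FALSE)
  if (any(a_sample < 0)) stop("'a_sample' must be >= 0", call. = FALSE)
  100 * (a_control - a_sample) / a_control
}

#' Total phenolic content as gallic-acid equivalents
#'
#' Converts a Folin–Ciocalteu absorbance to concentration through a linear
#' gallic-acid calibration, `((A - intercept) / slope) * dilution`.
#' `gallic_calibration()` fits the curve from standards by least squares.
#'
#' @param absorbance Sample absorbance at 765 nm.
#' @param curve A `"calibration_curve"` from [gallic_calibration()], or any
#'   list with `slope` and `intercept`.
#' @param dilution Dilution factor applied to the sample.
#' @return Concentration in the calibration's concentration unit
#'   (mg GAE/L for a curve fitted in mg/L).
#' @examples
#' tpc_gae(0.5, list(slope = 0.005, intercept = 0), dilution = 5)  # 500
#' @export
tpc_gae <- function(absorbance, curve, dilution = 1) {
  if (is.null(curve$slope) || curve$slope == 0)
    stop("calibration slope must be non-zero", call. = FALSE)
  intercept <- if (is.null(curve$intercept)) 0 else curve$intercept
  conc <- (absorbance - intercept) / curve$slope * dilution
  if (any(conc < 0))
    warning("absorbance below the calibration intercept: negative concentration",
            call. = FALSE)
  conc
}

#' @rdname tpc_gae
#' @param concentration Standard concentrations (>= 2 distinct values).
#' @export
gallic_calibration <- function(concentration, absorbance) {
  if (length(concentration) < 2L || length(unique(concentration)) < 2L)
    stop("need at least two distinct standards", call. = FALSE)
  f <- stats::lm(absorbance ~ concentration)
  sst <- sum((absorbance - mean(absorbance))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(f)^2) / sst else NA_real_
  structure(list(slope = unname(stats::coef(f)[2]),
                 intercept = unname(stats::coef(f)[1]), r2 = r2),
            class = "calibration_curve")
}
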