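# Shared fixtures: the packaged experiment and its fitted surfaces.
pj_factors <- parsley_factors()
pj <- parsley_juice()

fit_chl <- rsm(chlorophyll ~ time + amplitude + temperature,
               data = pj, factors = pj_factors)
fit_aa <- rsm(ascorbic_acid ~ time + amplitude + temperature,
              data = pj, factors = pj_factors)
fit_chl_mlr <- rsm(chlorophyll ~ time + amplitude + temperature,
                   data = pj, factors = pj_factors, order = 1)

# A plausible coded-basis quadratic truth (close to the chlorophyll surface)
# used wherever a known ground truth is needed.
truth_beta <- c(7.54, -0.41, -0.22, -0.04, -0.41, -0.47, -0.07,
                0.08, -0.23, 0.59)

random_quadratic_beta <- function() {
  # concave-ish quadratic with bounded coefficients
  c(runif(1, 5, 10), runif(3, -1, 1), runif(3, -0.8, -0.1), runif(3, -0.5, 0.5))
}
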