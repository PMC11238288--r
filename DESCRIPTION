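Package: rsmpso
Title: Response-Surface Modelling and Particle Swarm Optimization for
    Thermosonication Process Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing food bioprocess conditions from designed
    experiments. Builds rotatable three-factor central composite designs,
    fits first- and second-order response-surface models by ordinary least
    squares in coded units with a full analysis of variance including the
    lack-of-fit/pure-error decomposition and the R-squared family (ordinary,
    adjusted, PRESS-based predicted), computes model-adequacy metrics (RMSE,
    absolute average deviation), and maximizes fitted surfaces over a
    bound-constrained box with a particle swarm optimizer using a linearly
    decaying inertia weight. Includes spectrophotometric assay calculators
    (total chlorophyll, DCPIP ascorbic-acid titration, DPPH inhibition,
    Folin-Ciocalteu total phenolics), a synthetic-data generator with known
    ground truth for parameter-recovery studies, and a packaged
    thermosonicated parsley-juice experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
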