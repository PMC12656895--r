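Package: vpglu
Title: Population-of-Models Analysis of Glutamatergic Ventral Pallidum Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Conductance-based multicompartment modelling of glutamatergic
    ventral pallidum (VP) neurons. Builds a ball-and-stick cell with a
    myelinated axon, integrates the cable equation with backward Euler,
    measures current-clamp validation metrics (input resistance, F-I curve,
    ramp threshold, peak firing current, afterhyperpolarization), calibrates
    populations of depolarization-block (DB) and non-depolarization-block
    (NDB) models with an affine-invariant ensemble MCMC sampler, and
    perturbs calibrated populations with a parvalbumin calcium-buffering
    mechanism to test whether buffer expression converts one firing
    phenotype into the other.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
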