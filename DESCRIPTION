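Package: swimodel
Title: Mass-Density Cue-Integration Model of the Size-Weight Illusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a maximum-likelihood cue-integration account of
    human heaviness perception in which perceived heaviness is a weighted
    average of two Stevens power-law estimates, one derived from an
    object's mass and one from its density, with weights governed by the
    relative reliability of the two estimates (optionally with correlated
    noise). Provides the stimulus registries of the underlying
    magnitude-estimation and two-interval forced-choice experiments,
    geometric-mean standardization of free-modulus magnitude estimates,
    a multi-start random-perturbation least-squares fitter for the model
    parameters, point-of-subjective-equality prediction, cumulative-
    Gaussian psychometric analysis with an adaptive comparison-discarding
    routine, and a synthetic-data generator that emulates the experimental
    designs so that every pipeline stage can be tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
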