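Package: richlattice
Title: Spatial Ecological Regression of Species Richness on a Regular Lattice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling species-richness counts on a regular lattice
    with a Bayesian Poisson regression that combines categorical land-use and
    topographic covariates, a spatially structured Matern random effect built
    as a Gaussian Markov random field through the stochastic partial
    differential equation (SPDE) approach, an unstructured per-cell
    heterogeneity effect, and penalised-complexity priors on the field
    hyperparameters.  Includes a year-over-year daily temperature variation
    statistic with seasonal stratification, a mixed-model temperature trend
    estimator, Matern kriging of station summaries onto lattice cells, a fully
    parameterised synthetic-data generator for simulation studies, and CSV /
    GeoJSON input-output with a small pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    lme4,
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
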