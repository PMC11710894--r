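Package: gyrprey
Title: Prey Abundance and Gyrfalcon Occupancy Modelling for Arctic Tundra
    Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical models linking Arctic herbivore abundance to
    Gyrfalcon territory occupancy. Fits Poisson N-mixture time-removal
    models to point-count data partitioned into removal intervals
    (multinomial-Poisson factorized likelihood with an area offset),
    assesses fit by parametric-bootstrap Pearson chi-squared and the
    dispersion ratio c-hat, projects fitted models onto an 800 m
    covariate lattice with elevation and covariate-range masking,
    aggregates prey density within predator territories, and fits a
    stacked multi-year occupancy model with a year random intercept on
    occupancy and a territory random intercept on detection via a joint
    Laplace approximation. Includes a synthetic-data generator that
    reproduces the survey design (983 point-count sites with five 2-min
    intervals; 97 territories surveyed twice a year over six seasons)
    so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
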