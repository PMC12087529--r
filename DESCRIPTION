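Package: woodflow
Title: Circuit-Theory Woodland Connectivity and Invertebrate Occurrence Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the effect of woodland cover and
    circuit-theoretic landscape connectivity on the occurrence of
    woodland-associated invertebrate species. Provides a synthetic
    landscape and citizen-science record generator, an omnidirectional
    moving-window circuit model that computes cumulative current flow
    over a resistance surface, construction of detection/non-detection
    visit data with list-length effort classes, per-species Bayesian
    spatio-temporal logistic occurrence models fitted by Laplace
    approximation (with an MCMC cross-check backend), credible-interval
    based woodland-association classification, a measurement-error
    random-effects meta-analysis pooling species-level coefficients
    across recording schemes, and cover-by-connectivity prediction
    surfaces with posterior uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, Matrix, yaml, tiff
Suggests: testthat (>= 3.0.0), metafor, MASS, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'circuit.R'
    'covariates.R'
    'io.R'
    'meta.R'
    'methods-accessors.R'
    'occurrence.R'
    'pipeline.R'
    'surface.R'
    'synthetic-landscape.R'
    'synthetic-records.R'
    'utils.R'
    'visits.R'
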