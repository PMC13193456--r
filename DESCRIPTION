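Package: snakeOverlap
Title: Niche Models, Cost-Distance Ranges and Snake-Human Overlap
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for modelling the distributions of
    medically important venomous snakes and their overlap with human
    populations. Provides a Maxent-style penalized Gibbs niche model with
    linear, quadratic, product and hinge features; target-group background
    construction with latitudinal/longitudinal buffer sizing; cost-distance
    restriction of predicted ranges and splitting of multi-species
    modelling units with an overlap fade-out rule; the Snake-Human Overlap
    Index (SHOI, suitability times log human population density); climate
    projection ensembles summarized as cellwise quantiles; range-shift
    vectors with great-circle distance and bearing plus circular summary
    statistics; and model validation via AUC, partial ROC and comparison
    against expert-derived range polygons. A synthetic-data module
    generates environmental layers, occurrence records, population rasters
    and expert ranges with known ground truth so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, igraph, jsonlite, yaml
Suggests: testthat (>= 3.0.0), geosphere, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'grid-methods.R'
    'geo-io.R'
    'synthetic.R'
    'predictors.R'
    'background.R'
    'features.R'
    'enm.R'
    'postprocess.R'
    'exposure.R'
    'futures.R'
    'validation.R'
    'pipeline.R'
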