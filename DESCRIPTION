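Package: phenocube
Title: Mapping Invasive Buffel Grass from Vegetation-Index Time-Series Cubes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models and maps the occurrence of invasive buffel grass
    (Cenchrus ciliaris) in arid landscapes from dense satellite image time
    series. Dated multiband reflectance stacks are quality-filtered, turned
    into spatiotemporal matrices of vegetation indices (EVI, NBR, NDVI, NDWI),
    decomposed by truncated singular value decomposition into temporal modes
    and per-pixel spatial loadings, and classified with forward-stepwise
    logistic regression under the Bayesian Information Criterion, with a small
    tanh neural network as comparator. Fitted models are projected to per-pixel
    probability surfaces, thresholded occurrence maps and landscape-stratum
    summaries. A seeded generator of synthetic arid-zone scenes with
    rainfall-pulse phenology, fire scars and cloud dropout provides a fully
    reproducible test substrate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
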