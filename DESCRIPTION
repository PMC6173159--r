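Package: spotmetrics
Title: Quantification, Inheritance and Fitness Consequences of Animal Coat
    Spot Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for objective quantification of complex mammal coat spot
    patterns from photographs, and for downstream evolutionary analysis.
    Extracts dark spots from an analysis rectangle on a coat photograph,
    measures eleven scale-invariant shape and colour traits per animal
    (number, area, perimeter, ellipse angle, circularity, maximum caliper,
    Feret angle, aspect ratio, roundness, solidity, mode shade), estimates
    measurement repeatability and mother-offspring heritability by
    parent-offspring regression, groups animals into coat-pattern phenotypes
    with k-means and the gap statistic, and fits robust-design
    capture-mark-recapture models of age-specific apparent survival with
    temporary emigration, phenotype-group effects and spot-trait covariates,
    ranked by AICc with model averaging. A synthetic-data module generates
    spotted-coat images, trait tables and encounter histories with known
    ground truth so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    igraph,
    png,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    cluster
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
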