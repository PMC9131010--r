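Package: urbanstress
Title: Perceived Psychological Stress Mapping for Urban Streetscapes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Measures perceived psychological stress across an urban road
    network from the visual-element composition of street scenes. Provides
    fixed-interval sampling of road networks, conversion of semantic
    segmentation label rasters into 19-class coverage fractions, a
    human-machine adversarial scoring loop built on random-forest regression
    with out-of-bag diagnostics and indicator-based permutation variable
    importance, global Moran's I and local indicators of spatial association
    (LISA) on fixed-distance Manhattan weights, Jenks natural-breaks stress
    levels with hexagonal and district aggregation, and multiple linear
    regression of stress on element coverages with standardized betas, VIF
    and Durbin-Watson diagnostics. A synthetic-scene module generates road
    networks, compositional scene vectors, spatially autocorrelated latent
    stress fields and simulated raters so the full pipeline runs end to end
    without street imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    randomForest,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    ape,
    car,
    lmtest,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
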