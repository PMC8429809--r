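Package: allorings
Title: Root-Shoot Allometry from Tree-Ring Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing long-term and short-term root-shoot allometry
    of trees from multi-compartment ring-width series (stem, root collar, main
    root). Reads and writes Tucson/decadal ring-width files, aggregates and
    detrends series into chronologies, computes dendrochronological quality
    statistics (mean sensitivity, Gleichlaeufigkeit, Baillie-Pilcher t,
    cross-date index, pointer years, segment cross-dating), reconstructs
    annual radii, fits the log-log allometric mixed model with site
    interactions, derives annual allometric slopes and the percentage change
    in allometric slope (PCA) around a canopy-opening intervention, and
    models PCA as a function of tree size and edge position with Cook's
    distance outlier screening and backward AIC selection. A synthetic-data
    generator reproduces the statistical structure the analysis assumes so
    the full pipeline can be exercised and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
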