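Package: darkgaps
Title: Detection, Mapping and Drivers of Suspected AIS Disabling in Fishing Fleets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for intentional disabling of AIS
    (automatic identification system) transponders by fishing vessels. Detects
    transmission gaps in vessel ping streams, maps satellite reception quality
    (observed at 1 degree, interpolated to 0.25 degree with a thin-plate-spline
    radial basis function), filters and classifies gaps as suspected intentional
    disabling with a rule model selected by F0.5 under repeated k-fold
    cross-validation, spatially allocates the hidden time onto a quarter-degree
    grid by linear and rasterized-probability methods, maps the fraction of
    fishing activity obscured, and models spatial drivers of disabling with
    boosted regression trees (relative importance, partial dependence, AUC and
    true-skill-statistic evaluation). Includes a synthetic AIS world generator
    so every stage is testable without proprietary vessel-tracking data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    geosphere,
    xgboost,
    pROC,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
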