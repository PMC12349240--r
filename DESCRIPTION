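Package: hydrotherm
Title: Hydrothermal Indexes, Ensemble Distribution Modelling and Habitat
    Dynamics for Arid-Zone Shrubs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative biogeography toolkit built around Kira's warmth
    and coldness indexes and Xu's humidity index. Computes station-level
    hydrothermal indexes from monthly climate normals, interpolates them to
    regular grids by ordinary kriging, fits geographic-gradient regressions,
    derives per-species thermal profiles with peak-width-at-half-height
    optimal ranges and a five-type moisture-temperature classification,
    runs a presence/pseudo-absence ensemble species-distribution-modelling
    procedure with TSS-weighted consensus, and converts suitability grids
    into suitability classes, latitude-corrected areas, range-change maps
    and centroid-migration vectors. A synthetic-world generator with known
    ground truth makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    yaml,
    jsonlite,
    randomForest,
    xgboost,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
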