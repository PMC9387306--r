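Package: ryecolor
Title: Leaf-Color Quantification for Waterlogged Ryegrass Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for quantifying leaf color from raw
    camera imagery of harvested perennial ryegrass. Develops color-filter-
    array (Bayer) frames into color-corrected RGB images using gradient-
    corrected linear interpolation and a 24-patch chart-fitted affine color
    transform, segments leaf pixels with HSV gating and region-based active
    contours, reduces each plant to its median RGB, extracts a single
    "color intensity" axis with an uncentered principal component analysis,
    and relates that axis to phenotypic, environmental, genetic and
    temporal covariates via rank tests and a linear model with single-term-
    deletion Type II ANOVA and AIC model selection. A synthetic-scene and
    synthetic-phenotype generator with known ground truth makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    tiff,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
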