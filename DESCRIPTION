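Package: grazescape
Title: Coupled Remote-Sensing and Stable-Isotope Analysis of Herbivore
    Diet-Landscape Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for testing whether large-herbivore diets track the
    availability of grass in savanna landscapes. Classifies a landscape
    along the woody-cover gradient from dual-date multispectral composites
    (random-forest classification with confusion-matrix accuracy
    assessment), extracts land-cover composition in concentric circular
    buffers around faecal sample sites, computes a grassiness index,
    converts faecal carbon isotope ratios (delta 13C) to percent C4 grass
    intake through a two-endmember linear mixing model, and tests
    diet-landscape tracking with a locality-blocked permutation regression
    framework that is unbiased with respect to repeated collections at a
    sampling locality. Includes a synthetic-data generator (autocorrelated
    categorical landscapes and clustered faecal sampling) so that the full
    pipeline is testable without satellite imagery or field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    randomForest,
    sp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
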