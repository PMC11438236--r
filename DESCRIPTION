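Package: masshull
Title: Convex-Hull Volumetric and Stylopodial-Scaling Body Mass Estimation
    for Quadrupedal Tetrapods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates tetrapod body mass from minimum convex hulls of
    skeletal body segments and from combined humerus plus femur midshaft
    circumference, and compares the two approaches. Provides exact
    convex-hull volume and centroid computation for triangle meshes
    (OBJ/PLY/STL), whole-body segment models with per-segment densities
    and expansion factors, center-of-mass positional metrics relative to
    the acetabulum-glenoid transect, log10-log10 allometric scaling fits
    with percent-prediction-error accuracy and precision machinery,
    limb-bone robustness allometry, and a synthetic-data generator with
    analytic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
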