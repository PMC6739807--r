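Package: jellytag
Title: Behavior Classification and Orientation Analysis for Jellyfish
    Biologging Tags
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interpreting high-resolution motion-tag records from
    jellyfish and other soft-bodied zooplankton. Provides tilt-compensated
    orientation estimation from accelerometer and magnetometer channels,
    separation of static (gravity) and dynamic body acceleration with a
    linear-phase FIR filter, per-deployment pulse-cycle segmentation from the
    discrete cosine transform of dynamic acceleration, a 45-feature
    accelerometer and gyroscope featurization of each pulse period, quadratic
    discriminant analysis classifiers for tether influence and swim/drift
    activity selected by sequential forward selection under a nested
    cross-validated area-under-the-precision-recall-curve criterion, and
    downstream activity budgets, orientation summaries and rank-based group
    comparisons. A synthetic deployment generator with known ground truth
    supports development and validation where field recordings are
    unavailable.
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
    readr,
    rlang (>= 1.0.0),
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    MASS,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
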