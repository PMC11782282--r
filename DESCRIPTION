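Package: gazesal
Title: Fixation Saliency Analysis for Eye-Tracking Studies of Visual Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying visual attention to individual lower- and
    higher-order visual features from eye-tracking recordings. Detects
    fixations and saccades from raw 500 Hz binocular gaze streams using
    dispersion and kinematic thresholds, scores each fixation against
    feature-specific grayscale saliency maps (the fixation saliency value),
    aggregates values per participant and image, and compares groups with
    Mann-Whitney tests, Spearman correlations to functional-vision scores,
    covariate regression and a closed-form two-sample size calculation.
    Includes spatial-frequency (cycles-per-degree) analysis of stimulus
    images and a synthetic viewer simulator that generates gaze recordings
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
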