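Package: nbhfclick
Title: Narrow-Band High-Frequency Biosonar Click Analysis for Hydrophone Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of narrow-band high-frequency (NBHF)
    echolocation clicks recorded on vertical multi-element hydrophone arrays.
    Provides a synthetic-scene generator with known ground truth (directional
    Gaussian-envelope tone pips, circular-piston beam attenuation, spherical
    spreading with frequency-dependent seawater absorption, additive ambient
    noise), click source-parameter extraction (duration, peak and centroid
    frequency, bandwidths, received levels), time-difference-of-arrival
    localization with over-determined error estimates, on-axis click selection
    criteria, back-calculated apparent source levels, composite vertical beam
    patterns with piston-model fits and directivity index, audiogram-filtered
    species discrimination by centroid frequency (ROC criterion and Monte
    Carlo set classification), and an active-sonar detection-range model
    comparing NBHF and broadband click designs.
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
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
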