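Package: rangemargins
Title: Quantifying Species Range-Margin Shifts from Presence-Absence Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify range expansion at a species' distributional
    edge from georeferenced presence-absence surveys. Turns raw survey
    records into range-margin distance series (grid resampling, range-center
    centroids, percentile or top-k margin selection) and range-periphery
    occupancy series (minimum enclosing circles), fits five candidate trend
    models (constant, linear, quadratic, two-slope segmented, left-horizontal
    segmented) for Gaussian and binomial-logit responses with iterative
    breakpoint estimation and a pseudo-score test for the existence of a
    breakpoint, and ranks models by small-sample AICc and Akaike weights.
    Includes a synthetic-data generator emulating stasis-then-expansion
    range dynamics for method validation.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
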