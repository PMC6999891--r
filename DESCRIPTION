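Package: cd30nbhd
Title: Spatial Neighborhood Analysis of CD30-Positive Cells in Whole Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical analysis of spatial neighborhood preferences of
    immunostained cells in whole slide images of lymph node tissue.
    Segmented CD30-positive cells are classified into eight morphological
    profile classes from shape descriptors (area, eccentricity, solidity,
    maximal Feret diameter), nearest-neighbor tables are built under a
    distance cutoff, and favored/unfavored neighborhood relations are
    detected per image with exact binomial prediction intervals.
    Per-image significance calls are aggregated into diagnosis-level
    integer scores and directed preference networks.  Cell diameter
    distributions are corrected for an activated-lymphocyte background
    to estimate the proportion of tumor cells.  A synthetic cohort
    generator (complete spatial randomness, Thomas cluster processes,
    planted cross-class attraction and repulsion) provides calibrated
    test beds with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
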