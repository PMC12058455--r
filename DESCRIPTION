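Package: treelineform
Title: Quantifying Abruptness and Discreteness of Alpine Treeline Ecotones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify and classify the spatial form of alpine
    treeline ecotones from individual tree point patterns on hillslope
    transects. The transect is partitioned into elevational belts and
    square subplots; belt-wise canopy-height vectors (highest and
    second-highest subplot canopy height) are truncated at a forest
    cutoff and gap-smoothed, and the largest between-belt height decline
    yields four abruptness metrics (absolute and normalised, from the
    first and second maximum). Tree cover is rasterized as the union of
    circular crowns on a fine grid, averaged per subplot, and a
    three-parameter logistic is fitted along the elevation axis; its
    steepness quantifies discreteness. Threshold-based classifiers map
    the metrics to gradual/intermediate/abrupt and discrete/diffuse
    forms, with krummholz adjustments and validity diagnostics. A
    synthetic ecotone generator with known ground truth supports testing
    and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
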