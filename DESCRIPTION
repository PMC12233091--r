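Package: synaptrace
Title: Dendrite, Spine and Puncta Analysis for Fluorescence Microscopy Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless analysis engine for 2D multi-channel fluorescence
    time series of neurons. Traces dendritic medial axes as shortest paths
    on boundary-distance-weighted cost fields, segments dendrites by
    iterative ellipse growth against Canny edge maps, generates editable
    spine-head ROIs by eight-ray rule-counter growth, traces and segments
    spine necks, classifies spines from neck-to-head width ratios, corrects
    global and local (per-spine) motion by phase cross-correlation, and
    detects fluorescent puncta inside ROIs by Laplacian-of-Gaussian blob
    detection with per-ROI adaptive thresholds. Ships a synthetic image
    generator with known ground truth for end-to-end validation, ImageJ
    .roi import/export, and a scriptable pipeline with portable parameter
    records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    tiff,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
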