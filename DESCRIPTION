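Package: laminaseg
Title: Patch-Based Segmentation and Evaluation of Cortical Laminar Structure in Histology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable framework for segmenting the six Brodmann layers of the
    cerebral cortex in down-sampled Nissl-stained histology images. Provides
    overlapping-patch extraction with quality filtering, pluggable per-patch
    segmentation backends, heatmap-based stitching with locally adaptive
    thresholding, a complete overlap and surface-distance evaluation suite
    (IoU, Dice, recall, precision, Hausdorff, 95th-percentile Hausdorff,
    average symmetric surface distance, layer thickness), brain-region mask
    extraction from atlas overlays, anchor-based registration scoring, and a
    seeded six-layer cortex phantom generator so that every pipeline stage is
    testable without whole-brain data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    png,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
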