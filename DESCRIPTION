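Package: sppe
Title: Spatial Pyramid Partition Ensemble Classification of Flour Images
Version: 0.1.0
Authors@R: person("Flour", "Vision", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computer-vision pipeline for classifying granular-material
    images (barley flour: malting versus naked cultivars). Provides Otsu-based
    region-of-interest extraction, a three-level spatial pyramid partition
    (1 + 4 + 16 = 21 regions), a 55-dimensional colour/intensity/texture
    descriptor per region (HSV and CIE L*a*b* moments, histogram statistics,
    rotation-invariant uniform LBP, grey-level co-occurrence statistics and
    FFT power-spectrum statistics), and a weighted sub-region voting ensemble
    (SPPe) together with the traditional whole-ROI and concatenated spatial
    pyramid baselines. Includes a Kennard-Stone representative split,
    leave-one-sample-out and grouped k-fold evaluation with a hard leakage
    guard, confusion-matrix metrics, a seeded synthetic flour-image generator,
    and command-line entry points for the end-to-end workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    tools,
    FNN,
    glmnet,
    jsonlite,
    png,
    jpeg,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
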