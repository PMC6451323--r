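Package: vascq
Title: Vascular Segmentation, Stitching and Growth Modelling for
    Multi-Sample Light-Sheet Time-Lapses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify embryonic vascular volume growth from
    two-channel light-sheet time-lapse imagery of zebrafish. Implements
    self-supervised 3D vessel segmentation that learns per-voxel feature
    weights from a circulating red-blood-cell channel used as a luminal
    proxy, phase-correlation stitching of mosaic tiles initialised from
    stage positions, automated mosaic planning, backward region-of-interest
    propagation on maximum-intensity projections, isotropic volume
    quantification, and fitting and comparison of log-time-rescaled
    (log-logistic and log-normal) growth models against classical
    sigmoidal growth laws. A synthetic-data module generates tubular
    vascular phantoms with ground-truth masks, tile sets with known
    offsets and noisy growth series so the whole pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml,
    minpack.lm,
    igraph,
    EBImage,
    mgcv
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
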