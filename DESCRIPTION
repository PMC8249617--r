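Package: vasclear
Title: Vascular Network Tracing and Tracer Extravasation Quantification
    for Cleared-Tissue Microscopy
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of fluorescence microscopy of
    brain (tumor) vasculature in optically cleared tissue and in sections:
    a seeded synthetic phantom generator with exact ground truth, calibrated
    TIFF stack I/O, a trainable multiscale-filter-bank random-forest pixel
    classifier, a 3D extravasation-spot detection and morphometry pipeline,
    vascular mask postprocessing with adjustable lumen filling,
    skeletonization into a spatial vessel graph with per-segment length,
    tortuosity and diameter (including an exponential-decay diameter
    correction), and transcardial-perfusion-degree quantification from
    4-class section masks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
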