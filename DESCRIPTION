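Package: mitoscope
Title: Detection, Orientation and Spatio-Temporal Statistics of Cell
    Divisions in Epithelial Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for finding cell divisions in two-channel (junction +
    nuclear) fluorescence time-lapse movies of epithelia and for analysing
    their spatio-temporal organisation. Provides a ground-truthed synthetic
    epithelium simulator (divisions, wounds, motile false-positive bait,
    photobleaching, drift), focus-stack projection of z-stacks, construction
    of sliding-window clips and training targets, a configurable residual
    encoder-decoder dense-prediction network trained on the CPU, blob-based
    division calling with cross-frame suppression, nematic q-tensor
    orientation extraction, watershed segmentation and overlap tracking of
    cells, wound-referenced division-density bands, and space-time
    correlation functions of division density and orientation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
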