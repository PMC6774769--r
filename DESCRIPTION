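Package: SkinGNG
Title: Parametric Skin-Colour Segmentation and Growing Neural Gas Topology Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and reconstructs faces and hands in colour images and
    depth data. Fits single-Gaussian and EM-estimated Gaussian-mixture skin
    chrominance models in four colour representations (normalised RGB, HSV,
    CIE XYZ chromaticity, CIE L*a*b*), produces per-pixel skin probability
    maps and thresholded masks, evaluates them with TPR/FPR, ROC, IoU and
    Dice statistics, and learns the 2D topology of segmented regions or a
    coloured 3D mesh from point clouds with a growing neural gas network.
    Ships a synthetic-scene and point-cloud generator with exact ground
    truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    tools,
    MASS,
    Rcpp,
    png,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
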