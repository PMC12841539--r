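Package: maizeseg
Title: Segmentation and Damage Classification of Adhered Maize Kernels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Instance segmentation of touching (adhered) maize kernels in 2-D
    images and per-kernel mechanical-damage classification. Implements a hybrid
    pipeline: Otsu binarization with binary morphology, an improved
    marker-controlled watershed on the Euclidean distance transform (Sobel
    gradient surface available as an alternative flooding height), convexity
    defect detection with contour cutting to resolve residual adhesions, eight
    morphological shape descriptors per kernel, and a support vector machine
    classifier (linear, RBF and polynomial kernels). Ships a seeded synthetic
    scene generator with exact per-kernel ground truth, a full evaluation suite
    (confusion metrics, counting accuracy, IoU/Dice, instance matching) and the
    ablation variants of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
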