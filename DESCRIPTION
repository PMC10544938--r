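Package: PanicleScan
Title: On-Panicle Rice Grain Phenotyping from Calibrated Scan Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures rice grain phenotypes directly on intact panicles from
    visible-light scanner images, without threshing. Provides calibrated scan
    input/output (dpi to millimetre conversion), a synthetic scanned-panicle
    scene generator with exact ground truth, grain detection by Otsu
    segmentation with distance-transform watershed splitting plus a compact
    trainable two-stage detector with feature-pyramid fusion, occlusion
    restoration by least-squares ellipse completion plus a compact conditional
    GAN (U-Net generator, fused global/patch discriminator), a per-grain trait
    measurement pipeline (length, width, projection area, perimeter and
    derived shape quantities in physical units), aggregation to the fifteen
    panicle-level traits, thousand-grain statistics, and the full evaluation
    metric suite (R-squared, MAPE, RMSE, PSNR, SSIM, average precision).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
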