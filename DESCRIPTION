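Package: dermclass
Title: Dermoscopic Lesion Classification with Fuzzy Clustering and
    Manta-Ray-Optimized Cascade Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end pipeline for two-class (melanoma vs benign)
    classification of dermoscopic images: bilateral-filter denoising,
    fuzzy k-means (fuzzy c-means) lesion segmentation, compact
    convolutional feature extraction trained by stochastic gradient
    descent, and a cascade-forward neural network classifier whose
    weights are trained by Manta Ray Foraging Optimization with an
    error-rate fitness.  Includes a seeded synthetic lesion-image
    generator with ground-truth masks, confusion-matrix metric
    reporting with macro averages, ROC/PR curve data, stratified
    splitting, and a reproducible single-config pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    pROC,
    jpeg,
    optparse
Config/testthat/edition: 3
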