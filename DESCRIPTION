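Package: lrscnet
Title: Local-Reference Semantic-Code Classification of Breast Ultrasound Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Patch-based benign/malignant classification of breast ultrasound
    (BUS) lesion images designed for small labeled datasets. Class-tagged
    "local references" (prototype patches) are learned by a class-guided
    k-means-style clustering; a tied-parameter convolutional feature extractor
    with a learned relation head scores the similarity of every image patch to
    every reference; the per-patch similarities are binarized into a semantic
    code, and a training-free self-matching vote over the code's bits yields
    the final label. Includes a seeded generator of two-class speckle-texture
    phantom images with lesion masks so the whole train/encode/classify/
    evaluate loop runs without external data, plus confusion-matrix metrics
    and rank-based AUC with benign as the positive class.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
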