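Package: affssd
Title: Attention-Enhanced Feature-Fusion Single-Shot Detection for Low-Contrast Medical Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A single-shot multibox detector (SSD300, VGG16 backbone) augmented
    with parameter-free SimAM attention and a cascade of four forward stepwise
    feature-fusion modules, aimed at low-contrast targets such as the prostate
    capsule in endoscopic video frames. Provides the full detection stack in R:
    backbone and fusion-network builders with exact shape accounting, default-box
    generation, anchor matching, multibox loss with hard-negative mining,
    non-maximum suppression, Pascal-VOC average-precision evaluation, a seeded
    synthetic-scene generator with Pascal-VOC XML I/O, a momentum-SGD training
    loop, and an ablation-grid runner over attention/fusion layer subsets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    yaml,
    stats,
    utils,
    png,
    xml2,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
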