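Package: vitileaf
Title: Lightweight Coordinate-Attention Networks for Grape Leaf Cultivar
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, audits and trains lightweight convolutional networks for
    fine-grained grape (Vitis vinifera) leaf cultivar classification. Provides
    a from-scratch MobileNetV3-Small backbone with interchangeable attention
    blocks (squeeze-and-excitation, efficient channel attention, convolutional
    block attention, coordinate attention), a multi-branch Inception-style
    fusion stage with dual-attention filtering, and joint cross-entropy /
    center-loss supervision with class-center updates. Ships an exact
    trainable-parameter and multiply-accumulate auditor for all model variants
    and reference baselines, a stratified split and 5-fold assignment pipeline
    with field-style augmentation, and a procedural synthetic vineyard-leaf
    scene generator (lobed leaf silhouettes, natural-element backgrounds,
    controlled occlusion bands) so the full training pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    caret,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
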