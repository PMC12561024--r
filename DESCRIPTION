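Package: boneseg
Title: Bone Surface Segmentation in Pediatric B-Mode Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Automatic segmentation of the bone surface in 2-D B-mode
    ultrasound images with a lightweight tokenized-MLP encoder-decoder
    network (UNeXt-style), trained with a warm-up weighted binary
    cross-entropy followed by a dynamically blended centerline-Dice loss.
    Includes a synthetic bone-phantom generator (bright curvilinear echo,
    acoustic shadow, speckle, fascia distractors), topology-aware
    evaluation metrics (centerline Dice on morphological skeletons,
    directed mean surface distance in millimetres, signed probe-axis
    offset), group-aware stratified splitting, k-fold cross-validation
    and probability-averaged fold ensembles. The network, reverse-mode
    differentiation, AdamW optimizer and plateau learning-rate schedule
    are implemented natively in R and C++.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
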