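Package: caneratio
Title: Breakage and Impurity Ratio Estimation for Harvested Raw Sugarcane
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies breakage and impurity ratios of machine-harvested raw
    sugarcane from RGB images. A surface-density model (grams per pixel,
    Gaussian-fitted per material class) converts per-class pixel counts into
    mass estimates and into breakage and impurity ratios, with the full
    evaluation protocol (relative errors, regression, ANOVA). Pixel counts are
    supplied by a lightweight encoder-decoder semantic-segmentation network:
    a dilated MobileNetv2 backbone feeding an atrous-spatial-pyramid-pooling
    head with depthwise-separable convolutions and a strip-pooling branch,
    plus coordinate attention, trained with a combined focal and multi-class
    Dice loss. Includes a synthetic scene generator with PASCAL-VOC-style
    palette masks and the standard augmentations, so the whole pipeline is
    testable without access to the original imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    png,
    jsonlite,
    yaml,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
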