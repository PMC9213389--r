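Package: polypcnn
Title: Deep Ensembles of 3D Convolutional Networks for Colorectal Polyp
    Classification in CT Colonography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differentiates premalignant from benign colorectal polyps on CT
    colonography subvolumes with deep ensembles of small 3D residual
    convolutional networks. Provides two model variants (image-only and
    image-plus-segmentation two-channel input), a synthetic polyp phantom
    generator for end-to-end testing without patient data, train-validation
    resampled ensemble training with early stopping on validation AUC,
    Grad-CAM++ volumetric class-activation maps with a mask-coverage
    statistic, and ROC evaluation with threshold selection at a fixed
    sensitivity. Convolution forward and backward passes are implemented in
    C++ over single-precision BLAS matrix products.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
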