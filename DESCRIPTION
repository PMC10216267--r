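Package: GraMNet
Title: Gradational Modular Networks and Encoder-Decoder Liver Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for incremental, modular construction and training of
    convolutional neural networks (GraMNet): small SubNets are added in
    series or parallel to a frozen existing network and only the newest
    SubNet (plus the classification head) is trained at each stage. Also
    provides an encoder-decoder segmentation model (En-DeNet) with a
    combined binary cross-entropy and Dice loss, threshold binarization
    and connected-component fragment clearing, segmentation and
    classification evaluation metrics, and a synthetic CT-like phantom
    generator so every component is testable at desk scale without
    external data. The convolutional engine (convolution, batch
    normalization, max pooling, Adam, backpropagation) is implemented in
    the package with C++ kernels, giving the parameter-level control the
    staged freezing protocol requires.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    tiff,
    yaml,
    EBImage,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
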