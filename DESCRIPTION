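Package: sonnseg
Title: Cascaded Liver and Tumor CT Segmentation with Self-Organized
    Operational Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage (liver mask, then tumor-in-liver) semantic
    segmentation of abdominal computed tomography volumes using
    encoder-decoder networks whose decoder blocks are self-organized
    operational neural network (Self-ONN) layers: generative neurons whose
    nodal operator is a learned truncated MacLaurin series, so each
    connection applies a per-power kernel to integer powers of its input.
    Provides Hounsfield-unit windowing and NIfTI slice extraction,
    ResNet/DenseNet multi-scale encoders, U-Net, U-Net++, FPN and
    Self-ONN U-Net decoders with a two-channel SoftMax head, soft dice
    loss, overlap metrics with normal-theory confidence intervals and
    zero-dice accounting, a synthetic CT phantom generator, and a seeded
    training harness with k-fold cross-validation and early stopping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
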