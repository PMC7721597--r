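Package: kneecgan
Title: Conditional GAN and U-Net Segmentation of Multi-Tissue Knee MRI Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for multi-tissue semantic segmentation of sagittal knee
    MR slices with a conditional generative adversarial network (pix2pix-style
    U-Net generator plus PatchGAN discriminator) or a plain U-Net. Provides a
    colour-coded label codec for up to ten knee tissues (bones, cartilages,
    muscles, cruciate ligaments), declarative generator/discriminator
    architecture builders with analytic receptive-field computation,
    adversarial and pixel-wise training objectives with mid-training loss
    switching, volumetric evaluation metrics (Dice similarity coefficient,
    volumetric overlap error, average surface distance), a synthetic knee
    phantom generator for desk-scale experiments, and a training, transfer
    learning, inference and evaluation pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    RNifti,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, withr, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
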