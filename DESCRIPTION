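Package: res2fuse
Title: MR-CT Image Fusion with a Res2Net Autoencoder and Spatial Mean Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fuses pre-registered single-channel MR and CT slices with a
    convolutional autoencoder whose feature extractor embeds a scale-4
    Res2Net block, a parameter-free spatial-mean-attention fusion layer,
    and a four-layer convolutional reconstructor. The autoencoder is
    trained on single images with a hybrid structural-similarity plus
    pixel loss; the fusion layer is inserted only at inference. Includes
    the eight fusion-quality metrics customary in the field (average
    gradient, spatial frequency, entropy, mutual information, PSNR,
    SSIM, Qabf, VIFF), a paired t-test comparison utility, a seeded
    synthetic head-phantom generator producing registered CT/MR-like
    slice pairs, and a command-line interface covering phantom
    generation, training, fusion and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    RNifti,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
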