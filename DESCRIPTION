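Package: patkit
Title: Sparse-View Circular Photoacoustic Tomography Simulation and Deep-Learning Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end workbench for fast-scan circular photoacoustic
    tomography (PAT). Generates numerical initial-pressure phantoms (point
    targets, triangle outlines, cerebral-sinus-like vessel trees), simulates
    band-limited, finite-aperture, noisy A-line sinograms for single- and
    multi-transducer circular scan geometries with an analytical forward
    operator, reconstructs cross-sectional images with delay-and-sum
    beamforming, and restores sparse-view, low-SNR reconstructions with a
    hybrid dense U-Net (HD-UNet) trained against dense-scan ground truth
    using a composite image/Fourier mean-absolute-error loss. Includes the
    comparison architectures (FD-UNet, dilated dense U-Net, plain U-Net),
    repeated cross-validation with PCC/PSNR/SSIM/MAE reporting, and an ANSI
    skin maximum-permissible-exposure calculator for scan planning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse
Config/testthat/edition: 3
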