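Package: palpinv
Title: Inversion of Tactile Sensation Imaging for Tissue Inclusion
    Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the size, depth, and Young's modulus of a stiff
    spherical inclusion embedded in soft tissue from tactile data, the
    artificial-palpation analogue of manual breast examination.  Provides a
    linear-elasticity finite-element forward model of an elastic sensing
    probe indenting a tissue slab with an embedded inclusion, extraction of
    the three probe-deformation features (maximum deformation, total
    deformation, deformation area), a synthetic tactile-image renderer with
    the matching pixel-feature extractors, per-channel linear calibration
    between image and simulation feature spaces, and a small feed-forward
    neural network inverter trained by Levenberg-Marquardt or scaled
    conjugate gradient, validated by hold-out and leave-one-out
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Matrix,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
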