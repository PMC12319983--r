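Package: dwimotion
Title: Motion Correction and Model-Free Reconstruction for Multi-Shell
    Fetal Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for retrospective motion correction of multi-shell
    high-angular-resolution diffusion MRI acquired from moving subjects,
    with the fetal brain as the motivating application. Provides design of
    incrementally ordered multi-shell gradient sampling schemes by
    electrostatic-repulsion optimization, a simple-harmonic-oscillator
    (SHORE) q-space signal basis with weighted l2-regularized fitting,
    three-tier slice/voxel outlier weighting (modified Z-score, Gaussian
    mixture on prediction residuals, voxel-wise standardized residuals),
    rigid registration of each acquired volume to its model prediction
    with gradient-table rotation, Rician noise bias and B1 bias-field
    intensity corrections, a synthetic multi-tensor phantom simulator
    with known motion, slice dropouts and susceptibility distortion
    pairs, and SSIM/PSNR/motion-trace evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    mclust,
    pracma,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
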