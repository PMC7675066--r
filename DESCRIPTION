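Package: fanpat
Title: Photoacoustic Tomography with a Rotating Arc Array and Fan-Shaped
    Illumination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing and reconstruction toolkit for
    photoacoustic tomography on a rotating arc-array breast scanner with a
    fan-shaped diffuse illuminator. Provides a voxelized wire-phantom
    simulator with a band-limited acoustic forward model, Butterworth and
    truncated-SVD denoising of RF channel data, universal back-projection
    with solid-angle and Gaussian transducer-directivity weighting,
    diffusion-approximation modeling of the spatially non-uniform optical
    fluence with per-pose compensation, and tomographic image-quality
    metrics (SNR/FWHM, RMSE, SSIM, relative image error, depth-resolved
    error shells).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    signal,
    jsonlite,
    yaml,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
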