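Package: moco4d
Title: Fast Motion-Compensated 4D Cone-Beam CT Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for respiration-resolved (4D) cone-beam CT: simulation of
    a deformable digital thorax phantom with ground-truth motion, FDK
    reconstruction of phase-binned projections, self-supervised streak
    artifact reduction trained on pseudo-average/time-average image pairs,
    deep groupwise deformable registration of the phase images to an
    implicit mean template (one-shot patient-specific and pre-trained
    population modes), composition of the resulting displacement fields
    into an inter-phase motion model, and motion-compensated FDK
    reconstruction via warped backprojection. Includes target registration
    error, mean-aligned RMSE, PSNR and scale-searched SSIM evaluation plus
    DIR-Lab-style landmark I/O.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
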