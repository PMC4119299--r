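Package: tiltcorr
Title: Rotation-Axis Misalignment Correction for Parallel-Beam
    Phase-Contrast CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Marker-free geometric correction of rotation-axis misalignment
    in parallel-beam (in-line X-ray phase-contrast) computed tomography.
    Estimates the in-plane flip angle and lateral offset of the rotation
    axis from the mirror symmetry of the 0 and 180 degree projections by a
    two-step iterative scheme (reflective resampling followed by row-wise
    cross-correlation and a linear fit), corrects the tilt series by the
    inverse transform, reconstructs slices by filtered back-projection with
    a Ram-Lak filter, and evaluates reconstructions with mean SSIM and
    mutual information. Includes a deterministic simulator (modified 3D
    Shepp-Logan phantom, parallel-beam projection, controlled misalignment
    injection) for validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
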