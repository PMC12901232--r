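Package: cardiosync
Title: Adaptive Detection of Quiescent Cardiac Phases in Free-Running MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated, heart-rate-variability-adaptive detection of quiescent
    cardiac phases (end-systole, mid-diastole, end-diastole) from free-running
    3D radial cardiac MRI self-gating data. Builds synchronicity maps from
    preliminary CINE reconstructions (per-voxel cardiac phase of the intensity
    minimum, grouped by 26-connectivity), refines them with a parametric
    systolic-interval filter, detects quiescent timepoints and intervals on the
    averaged left-ventricular time curve, and maps them to per-beat adaptive
    data acceptance windows. Includes a full numerical simulation framework
    (beating analytic torso phantom with programmable RR, heart-rate
    variability and left-ventricular volume curve; spiral phyllotaxis 3D
    radial trajectory; gridding NUFFT sampling and reconstruction) with ground
    truth export, reference manually-parameterized reconstructions, and the
    validation metrics (temporal error, volumetric error, coronary vessel
    sharpness).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    optparse
Config/testthat/edition: 3
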