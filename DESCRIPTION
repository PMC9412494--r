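Package: kinegait
Title: Markerless Gait Analysis from Depth-Camera Skeletal Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes spatiotemporal gait parameters, center-of-mass sway,
    arm-swing amplitude metrics (linear and angular), absolute symmetry
    angle (ASA) asymmetry indices, and arm-arm / arm-leg synchrony indices
    from time-stamped 3D skeletal joint trajectories such as those produced
    by depth-camera body-tracking systems. Includes trial JSON input/output,
    uniform resampling and zero-phase low-pass filtering, restriction of the
    analysis to a virtual gait analysis path, ankle-based gait event
    detection, a parametric synthetic-walking simulator with closed-form
    ground truth for validation, and a two-group statistical comparison
    report (Mann-Whitney, Student's t, Shapiro-Wilk, Spearman and Pearson
    correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    grDevices,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
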