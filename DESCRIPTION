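Package: hemoflow
Title: Fluorescent Particle Tracking Velocimetry for Insect Wing Hemolymph
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies hemolymph microcirculation in insect wing vein
    networks from fluorescence time-lapse image stacks. Provides a synthetic
    scene generator (stylized five-region wing venation, pulsatile/aperiodic/
    leaky local flow behaviors, fluorescence rendering with photobleaching,
    uneven illumination and sensor noise), Hessian-eigenmap particle
    detection, multi-parametric frame-to-frame linking with globally optimal
    assignment, per-trajectory kinematics (instantaneous velocity, moving-mean
    smoothing, pulse frequency by normalized peak counting), and per-region
    hemodynamic summaries including Peclet, Reynolds and Womersley numbers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    yaml,
    pracma,
    igraph,
    matrixStats,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
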