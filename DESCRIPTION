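Package: arthroguide
Title: Haptic Force-Guidance Training Tools for Arthroscopic Inspection Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for experience-based arthroscopic skill
    training. Resolves a fiducial-marker trajectory from a two-camera rig
    with hold-last-pose dropout handling, smooths and compresses the
    recorded expert path with a least-squares NURBS fit (the central
    'nurbs_curve' model object), computes three-mode virtual-fixture
    guidance forces (attractive, static contour-error, time-dependent
    tracking-error), simulates a noisy trainee as a damped point mass under
    guidance, and scores sessions with the normal path error skill metric
    and cohort summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    splines,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
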