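Package: ogdist
Title: Object-Gaze Distance Analysis for Mobile Eye Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the Object-Gaze Distance (OGD): the minimal 2D
    Euclidean pixel distance between each fixation's gaze coordinate and
    the segmented mask of each area of interest (AOI) in scene-camera
    video, turning one-to-one AOI Hit mapping into a continuous
    per-fixation, per-object distance series. Includes camera geometry and
    visual-field thresholding (foveal, parafoveal, perifoveal,
    near-peripheral), fixation-rate curves over a distance-threshold sweep,
    AOI Hit extraction, mask intersection-over-union, rule-based detection
    of multi-object gaze patterns (glance, convergence, joint excursion,
    disappearance), readers for fixation tables and segmentation masks
    (label PNG and COCO-style JSON), a synthetic scene generator with
    analytic ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
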