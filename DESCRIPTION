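Package: camangio
Title: Virtual Angiography and Vessel Annotation for Ultrasound Cine Loops
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Vessel enhancement of B-mode ultrasound cine loops by
    accumulation of absolute temporal finite differences (virtual
    angiography), together with manual and semi-automatic vessel
    annotation: interpolated boundaries and curves, active-contour
    segmentation of large chorioallantoic-membrane (CAM) vessels,
    skeleton-based microvessel centerlines, and vascular network
    quantification (length, diameter, branch points). Includes a
    deterministic speckle-flow cine simulator with analytic ground truth
    for end-to-end validation, lossless multi-frame TIFF input/output,
    JSON annotation persistence and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    tools,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Visualization, Segmentation, Preprocessing
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'cine-io.R'
    'angiography.R'
    'splines.R'
    'snake.R'
    'skeleton.R'
    'metrics.R'
    'synth.R'
    'overlay.R'
    'cli.R'
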