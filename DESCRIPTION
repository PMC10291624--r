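Package: plantaug
Title: Data Augmentation for Labeled Plant Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for 3D data augmentation of labeled plant point clouds used
    in semantic plant-part segmentation. Provides a labeled point-cloud data
    model with normalization and 51-channel feature assembly (position, surface
    normal, fifteen-camera RGB), seven global augmentations (random
    down-sampling, jittering, xy-scaling, rotation, translation, cropping,
    brightness adjustment), leaf-geometry extraction (base point, principal
    axis, phyllotactic orientation and angle, rank), three leaf-level
    augmentations (leaf translation, rotation about the vertical or principal
    axis, and within-cultivar leaf crossover), per-class F1 evaluation, a
    procedural synthetic tomato-plant generator with ground truth, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
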