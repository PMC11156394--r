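Package: pestdet
Title: Two-Stage Farmland Pest Detection with Shifted-Window Attention and
    Neighborhood-Autocorrelation Feature Enhancement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A CPU-scale implementation of a two-stage object detector for
    farmland pest monitoring. Features are extracted by a hierarchical
    shifted-window multi-head self-attention backbone, enhanced by a
    neighborhood autocorrelation self-attention neck (sliding-window
    contextual features fused into a feature pyramid P3-P6), and decoded by
    a region proposal network followed by a three-stage cascade of detection
    heads with rising IoU thresholds and linear soft non-maximum
    suppression. Includes a procedural synthetic-scene generator with exact
    ground truth, copy-paste class balancing for imbalanced datasets,
    online photometric augmentation, COCO JSON input/output, training with
    momentum SGD and a step learning-rate schedule, and mean-average-
    precision evaluation. All network layers run on a built-in reverse-mode
    automatic differentiation engine over base R arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    yaml,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
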