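Package: sonopool
Title: Frame-Pooled Classification of Ultrasound Sweep Videos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Binary injury classification of B-mode ultrasound sweep videos by
    temporal frame pooling. Consecutive grayscale frames are stacked as the
    channel dimension of a single convolutional-network input so that one
    prediction integrates many probe angles; per-window softmax confidences are
    averaged into a per-video score and thresholded. The package provides a
    synthetic speckle-sweep generator with a controllable intermittently
    visible free-fluid cue, sliding-window pooling with end padding, a compact
    channel-patched CNN trained natively in R (Kaiming initialization, Adam,
    early stopping, temporally consistent augmentation), first-convolution
    kernel inflation for adapting RGB backbones to n-channel input, per-video
    aggregation, ROC/threshold optimisation, and an exact McNemar test for
    paired classifier comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, tools, EBImage, yaml, jsonlite
Suggests: testthat (>= 3.0.0), pROC, optparse, withr
Config/testthat/edition: 3
biocViews: Classification, Visualization
RoxygenNote: 7.3.3
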