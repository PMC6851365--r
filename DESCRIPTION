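Package: phacoseg
Title: Real-Time Surgical Phase Segmentation for Cataract Surgery Video
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Per-frame three-class recognition of cataract-surgery phases
    (continuous curvilinear capsulorrhexis, nuclear extraction, others) from
    1 FPS video frames, trailing moving-average smoothing of the classifier
    score stream, and extraction of phase start/end times, together with the
    evaluation metrics used for this task (per-class correct-response rates
    and boundary mean absolute errors). Includes a seeded synthetic-surgery
    generator (timelines, confusion-model score streams, rendered toy frames)
    so the whole pipeline is testable without clinical video, and a small
    Inception-style convolutional network trainable at toy scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
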