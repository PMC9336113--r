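Package: compens2d
Title: Compensation Assessment for Upper-Extremity Rehabilitation from 2D Video Keypoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frame-level detection of compensatory motion patterns (trunk
    forward/backward displacement, trunk rotation, shoulder elevation, trunk
    tilt) in upper-extremity stroke rehabilitation exercises, from 2D body
    keypoints extracted from monocular video. Reads the OpenPose BODY_25 JSON
    dialect, cleanses multi-skeleton frames (ghost removal, patient selection,
    confidence filtering), normalizes keypoints to a spine-scaled body frame,
    computes per-scenario kinematic variables, and classifies each frame with
    either an interpretable rule-based multilabel classifier or a two-stage
    neural approach (binary compensation gate followed by a one-vs-rest
    multilabel classifier). Includes micro-averaged multilabel metrics,
    Hamming loss, leave-one-subject-out and leave-one-exercise-out
    cross-validation, a synthetic keypoint-sequence generator with scripted
    compensation episodes and ground-truth labels, and a reflex-agent virtual
    coach state machine that turns frame labels into corrective feedback
    events.
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
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
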