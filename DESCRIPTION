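Package: spinekin
Title: Equine Spinal Kinematics from Optical Motion Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies range of motion and between-measurement variability of
    equine back and pelvic kinematics at trot from labelled 3D marker
    trajectories. Computes projection angles (whole-back and segmental
    flexion-extension and lateral bending, pelvic roll/pitch/yaw, body
    tracking, head swivel) in a heading-based, body-lean-corrected reference
    frame, segments trials into strides from vertical sacrum displacement,
    aggregates per-stride range of motion to measurement means, and provides
    the repeated-measures statistics used for normal-range studies:
    condition-wise percentile summaries, an offset-adjusted mixed-model
    variability analysis with back-transformed 95% prediction limits, and
    per-condition intraclass correlation coefficients. Includes a kinematic
    trot simulator with known ground truth so every pipeline stage can be
    tested without motion-capture hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    lme4,
    lmerTest,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    readxl,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
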