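Package: gazecaps
Title: Capsule-Network Emotion Classification from Eye-Tracking Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Emotion-state classification from eye tracking alone: velocity
    threshold (I-VT) fixation/saccade event detection, sliding-window moment
    statistics of pupil diameter and ocular events, rolling temporal feature
    doubling, one-way ANOVA feature screening, and a capsule network with
    adaptive dynamic routing followed by an MLP head trained under a joint
    margin plus weighted cross-entropy loss. Includes a synthetic gaze
    generator with class-dependent fixation, saccade and pupil statistics so
    the full pipeline can be exercised without any recorded dataset, SMOTE
    class balancing, stratified and grouped cross-validation, and a small
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
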