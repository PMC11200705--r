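Package: imugait
Title: Gait-Cycle Segmentation and Transformer Classification of Walking
    Independence from Body-Worn Inertial Sensors
Version: 0.1.0
Authors@R:
    person("imugait", "maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for classifying hospitalized patients' walking-independence
    level (walking acquired vs not acquired) from eight body-worn inertial
    measurement units recorded during the 10-m walk test and the Timed
    Up-and-Go test. Provides zero-phase high-pass filtering, initial-contact
    detection from the differentiated combined ankle acceleration, Timed
    Up-and-Go sub-phase segmentation from lumbar angular velocity, left
    gait-cycle extraction, amplitude normalization to the unit interval with a
    0.5 baseline, constant-value padding, uniform-noise augmentation, sensor
    masking, a Transformer encoder classifier trained from scratch with
    hand-written backpropagation, leave-one-subject-out cross-validation with
    pooled confusion-matrix metrics, and a sensor-ablation sweep. Includes a
    synthetic cohort generator with ground-truth gait events so the whole
    pipeline can be exercised and tested without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
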