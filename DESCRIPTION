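Package: babymotion
Title: Automated Infant Movement Analysis for Cerebral Palsy Risk Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies spontaneous infant movement from 2D video and models
    cerebral palsy risk from the resulting kinematic features. Frames are
    skin-segmented with a chrominance Gaussian model, dense inter-frame
    displacement is estimated with a pyramidal Lucas-Kanade optical flow,
    and per-frame quantity-of-motion and directional velocity indices are
    summarized per video and per patient. A logistic risk-model workflow
    reproduces the published development protocol: univariate screening,
    variance-inflation-factor pruning, backward selection, bootstrap
    optimism correction of the C-statistic, Hosmer-Lemeshow fit testing,
    and ROC-derived classification metrics with exact binomial confidence
    intervals. Phantom-video and cohort simulators provide ground-truth
    test beds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, png, yaml, EBImage, MASS
Suggests: testthat (>= 3.0.0), pROC, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
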