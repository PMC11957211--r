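Package: valenceDynamics
Title: Neural and Facial Trajectory Analysis of Stress-Induced Anhedonia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal Pavlovian reward/punishment
        discrimination experiments in chronically stressed mice: sucrose
        preference based behavioral phenotyping via k-means clustering with
        within-cluster sum-of-squares elbow model selection, lick peri-stimulus
        time histograms, geometric social-interaction scoring, principal
        component state-space trajectories of calcium-imaging neural
        populations (trajectory length, bin-by-bin distance, leave-one-animal-
        out resampling, ROI-matched reward/punishment length ratios), facial
        keypoint feature extraction (distances, angles, kinematics, region
        areas) with Savitzky-Golay smoothing and spout-based calibration, and
        per-time-bin cross-validated auROC phenotype decoding against
        shuffled-label nulls. Includes a seeded synthetic cohort generator
        that plants phenotype- and epoch-dependent effects so the full
        pipeline is testable end to end without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    signal,
    glmnet,
    pROC,
    withr,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
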