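Package: stenoscore
Title: Automated Posterior-Circulation Stenosis Scoring and Blood-Pressure
    Based Cognitive Impairment Risk Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies focal stenosis of the posterior circulatory arteries
    (basilar artery and both posterior cerebral arteries) from 3D
    time-of-flight MRA-like volumes by isotropic resampling, threshold and
    watershed segmentation, topology-preserving skeletonization, centerline
    graph construction, artery extraction, cross-sectional straightening and
    a diameter-ratio stenosis score. Couples the imaging score with repeated
    blood-pressure measurements (pulse pressure, mean arterial pressure,
    pulse pressure index), nested case-control matching, logistic
    association models with odds ratios, Spearman correlation screens, and
    four-learner cross-validated risk prediction with ROC/AUC and DeLong
    comparisons. Ships ground-truthed synthetic vessel phantoms and cohort
    simulators so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    pROC,
    rpart,
    randomForest,
    e1071,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
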