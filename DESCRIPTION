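Package: TubeLineQC
Title: Rule-Based Position Assessment of Tubes and Lines on Chest Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-segmentation assessment of endotracheal tubes, central venous
    catheters and nasogastric tubes on chest radiographs. Extracts tip
    coordinates from per-class binary mask channels by connected-component
    analysis, measures metric distances from tube tips to anatomical reference
    landmarks (carina, cavoatrial junction, gastro-esophageal junction), applies
    the RANZCR-CLiP position criteria as a deterministic rule engine that
    corrects multilabel classifier scores, and evaluates systems with bootstrap
    ROC-AUC confidence intervals, landmark mean absolute errors, paired tests
    and subgroup stratification. Includes a Hanley-McNeil AUC sample-size
    calculation and a synthetic cohort generator (landmarks, rasterized tube
    masks, binormal classifier scores, reader noise) so the whole pipeline is
    exercisable without image data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    png,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
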