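# TubeLineQC

Rule-based position assessment of tubes and lines on chest radiographs.

ICU chest radiographs are read first to check life-support hardware: the
endotracheal tube (ETT) should end 3.5–7 cm above the carina, the central
venous catheter (CVC) tip should sit in the SVC above the cavoatrial
junction, and the nasogastric tube (NGT) should reach at least 10 cm beyond
the gastro-esophageal junction. Deep-learning classifiers score these
RANZCR-CLiP position categories but often degrade on local ICU populations;
the geometric criteria themselves transfer perfectly. TubeLineQC implements
the post-network stage: it extracts tube-tip coordinates from per-class
binary mask channels by 8-connected component analysis, measures metric
tip-to-landmark distances (mm, via the DICOM pixel spacing), applies the
position criteria as a deterministic rule engine, and corrects the
classifier's scores where the geometry contradicts them — upgrading, never
downgrading, by swapping the two implicated label scores.

Around that core it provides the full study harness: one-vs-rest
Mann–Whitney AUCs with 1000-resample bootstrap percentile CIs (group
averages bootstrapped as their own statistic), landmark mean absolute
errors with paired t-tests, subgroup stratification, Hanley–McNeil AUC
sample-size calculation, and a seeded synthetic generator that produces
landmarks, rasterized mask channels and binormal classifier scores with
known ground truth, so the whole pipeline runs and is tested without any
image data.

For whom: developers and evaluators of catheter-position AI who need the
distance rules, the correction step and the evaluation statistics as
auditable, deterministic code.

## Worked example

Assess one radiograph from its mask channels, landmarks and classifier
scores:

```r
library(TubeLineQC)

meta  <- ImageMeta(512, 512, 0.7, imageId = "example")     # 0.7 mm/px
lm    <- LandmarkSet(carina = c(260, 150),
                     cavoatrialJunction = c(320, 230),
                     geJunction = c(235, 360))
masks <- MaskChannelSet(meta,
  ettTip  = rasterizeDisc(c(262, 121), 512, 512, 3),       # ~20 mm above carina
  cvcTip  = rasterizeDisc(c(318, 209), 512, 512, 3),       # ~15 mm above CAJ
  cvcLine = rasterizePolyline(cbind(seq(0, 318, length.out = 300),
                                    seq(70, 209, length.out = 300)), 512, 512, 3))

s <- setNames(rep(0.05, 11), RANZCR_LABELS)
s[c("ETT_Normal", "ETT_Borderline", "ETT_Abnormal")] <- c(0.81, 0.12, 0.04)
s[c("CVC_Normal", "CVC_Borderline", "CVC_Abnormal")] <- c(0.74, 0.18, 0.06)

res <- classifyImage(masks, lm, ClassScores(s), swanGanz = FALSE)
res$decisions$ETT
#> RuleDecision [ETT]: geometry Borderline; final label ETT_Borderline
#>   d_vertical = 20.3 mm, d_euclidean = 20.3 mm; fired: ETT_LOW
res$decisions$CVC
#> RuleDecision [CVC]: geometry Normal; final label CVC_Normal
#>   d_vertical = 14.7 mm, d_euclidean = 14.8 mm; fired: (none)
round(scoreVector(res$adjustedScores)[1:3], 2)
#>     ETT_Normal ETT_Borderline   ETT_Abnormal
#>           0.12           0.81           0.04
```

The ETT tip measures 20.3 mm above the carina — inside the "less than
3.5 cm" borderline band — so `ETT_LOW` fires and the Normal/Borderline
scores are swapped: the prediction is upgraded to `ETT_Borderline` while
the score set is preserved. The CVC tip is 14.7 mm above the cavoatrial
junction, which is normal; nothing fires.

The design sample-size computation (detect an AUC of 0.9 against a null of
0.7, two-sided alpha 0.05, power 0.8, 5% abnormal prevalence):

```r
aucSampleSize(0.9, 0.7, alpha = 0.05, power = 0.8, prevalence = 0.05)
#> $nPos  15    $nNeg  285    $nTotal  300    $achievedPower  0.818
```

— 15 positives and 285 negatives, 300 cases in total.

A full synthetic cohort and its evaluation:

```r
sim <- simulateCohort(SimConfig(nImages = 303, seed = 7))
rep <- evaluateCohort(sim$truth, sim$scores, nBoot = 1000, seed = 7)
rep                        # per-label and group AUCs with bootstrap CIs
writeEvalReport(rep, "report")   # JSON + CSV + reproducibility manifest
```

A command-line front end (`inst/cli/tubelineqc.R`) exposes the same
pipeline as `simulate`, `extract`, `classify`, `evaluate` and `power`
subcommands.

## Package layout

* `R/AllClasses.R` — S4 containers: `ImageMeta`, `LandmarkSet`,
  `MaskChannelSet`, `ClassScores`, `RuleConfig`, `RuleDecision`
* `R/geometry.R` — signed vertical and Euclidean tip-to-landmark distances
* `R/mask-extraction.R` — 8-connected components, tip selection, thinning,
  skeleton arc lengths, NGT tip recovery
* `R/rules.R` — the position criteria as a rule engine plus score correction
* `R/evaluation.R` — AUC, bootstrap CIs, group averages, MAE, paired tests,
  stratification
* `R/power.R` — Hanley–McNeil variance and sample-size search
* `R/synthetic.R` — the seeded cohort generator
* `R/io.R` — PNG masks, landmark JSON/CSV/CVAT-XML, DICOM pixel spacing,
  scores, reports
* `vignettes/tube-line-assessment.Rmd` — the methods vignette: model,
  conventions, parameter defaults and limitations
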