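---
title: "Rule-based position assessment of tubes and lines on chest radiographs"
author: "TubeLineQC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based position assessment of tubes and lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TubeLineQC)
```

## The problem

Portable chest radiographs of intensive-care patients are read first of all
to confirm that life-support hardware sits where it should: the endotracheal
tube (ETT) a few centimetres above the carina, the central venous catheter
(CVC) tip in the superior vena cava above the cavoatrial junction, the
nasogastric tube (NGT) well past the gastro-esophageal junction. Deep
segmentation networks can delineate these devices, and multilabel
classifiers can score each RANZCR-CLiP position category, but a classifier
trained elsewhere often degrades on a local ICU population. The geometric
criteria themselves, however, transfer perfectly: they are statements about
distances between a tube tip and a reference landmark.

TubeLineQC implements everything *downstream* of the neural networks: given
per-class binary mask channels, landmark coordinates and classifier scores,
it extracts tip coordinates, measures metric distances, applies the position
criteria as a deterministic rule engine, corrects the classifier's scores
where geometry contradicts them, and evaluates the result with the study
machinery of bootstrap ROC-AUCs, landmark errors and subgroup
stratification. A synthetic generator produces all of these inputs with
known ground truth, so the entire pipeline is testable without any image
data.

## Coordinates, spacing and distances

All coordinates are 0-based raster coordinates: origin at the top-left, `x`
rightward, `y` downward, so "above" (cranial) means smaller `y`. Pixel
spacing in mm/px is mandatory — the criteria are denominated in centimetres
— and is never defaulted silently: it comes either from DICOM metadata
(`PixelSpacing`, with `ImagerPixelSpacing` as fallback) or from an explicit
configuration value, DICOM winning (with a warning) when both are present
and disagree by more than 1%. Anisotropic spacing is supported; a single
value is applied to both axes.

Two distances are always computed and stored per tube: the signed vertical
(cranio-caudal) separation, positive when the tip is cranial to its
landmark, and the Euclidean distance. The rules use the vertical separation
by default because the criteria are phrased as "above"/"below"; overlays and
reports quote the straight-line distance. The choice is a configuration
flag (`distanceMode`), since the original phrasing does not pin it.

## The rule table

The engine encodes the RANZCR-CLiP criteria as distance bands with stable
rule identifiers:

| Tube | Normal | Borderline | Abnormal |
|------|--------|------------|----------|
| ETT | 3.5–7 cm above the carina | under 3.5 cm (`ETT_LOW`) or over 7 cm (`ETT_HIGH`) | at/below the carina (`ETT_BELOW_CARINA`); at T1 level or above (`ETT_T1_HIGH`, needs the optional T1 annotation) |
| NGT | ≥ 10 cm beyond the GE junction | beyond but < 10 cm (`NGT_SHORT`) | above the junction (`NGT_ABOVE_GEJ`) |
| CVC | above the cavoatrial junction | below it within the upper right atrium (`CVC_BELOW_CAJ`); above the aortic-arch margin when annotated (`CVC_ABOVE_ARCH`) | deeper than the upper-third band (`CVC_BELOW_RA_THIRD`) |

The 3.5 and 10 cm figures are the standard centimetre surrogates for "two"
and "four posterior ribs"; rib counting itself is out of scope. An NGT
whose largest line component touches the film edge with no in-field tip and
under 10 cm visible is *IncompletelyImaged* (`NGT_INCOMPLETE`). Swan-Ganz
catheters are Normal by convention (`SWAN_GANZ_NORMAL`): their sheath end
cannot be delineated. A rule whose landmark is absent is skipped —
the category becomes *Indeterminate*, never a guess.

Numerical conventions worth stating explicitly:

* **Band edges.** The borderline clauses are strict inequalities, so a tip
  at exactly 3.5 or 7 cm is Normal by default
  (`boundaryInclusiveNormal = TRUE`; configurable).
* **A tip exactly at the GE junction** (advancement 0) counts as
  Borderline: it has reached the junction but not advanced, and this keeps
  the category map total over all real distances.
* **"Upper 1/3 of the right atrium"** has no landmark in the data model; a
  configurable band below the cavoatrial junction stands in
  (`raUpperThirdMm`, default 25 mm — an engineering default, not a measured
  anatomical value).
* The CVC vessel-wall-angle criterion and coil/kink or aberrant-vessel
  detection are **not** evaluated; they require vessel anatomy that tip
  coordinates cannot supply. CVC geometry is therefore deliberately
  conservative.

## Score correction

The multilabel classifier emits one sigmoid score per label (no sum-to-one
constraint). Where the geometric category is *strictly worse* than the
category currently winning the scores (Normal < Borderline < Abnormal), the
two implicated scores are swapped. A swap is deterministic, keeps the
adjusted scores a permutation of the originals within the tube's group, is
idempotent, and never downgrades: geometry can only push a prediction
toward a worse category, which is the clinical reading of "upgrading" a
misplaced tube. *Indeterminate* and *IncompletelyImaged* geometry leaves
scores untouched. With `enabledRules = character(0)` the engine still
measures and reports distances but corrects nothing, so the same code path
expresses both the plain pipeline and the rule-based system.

```{r}
s <- setNames(rep(0.05, 11), RANZCR_LABELS)
s[c("ETT_Normal", "ETT_Borderline")] <- c(0.8, 0.15)
out <- applyRules(ClassScores(s), list(ETT = classifyEtt(20)))
scoreVector(out$adjustedScores)[1:3]
out$decisions$ETT
```

## Tip extraction from mask channels

The channel scheme separates masks by class: `ngt_line`, `cvc_line`,
`cvc_tip`, `ett_tip`. Connected components are labelled with
**8-connectivity** throughout — thin rasterized catheters run diagonally and
4-connectivity fragments them — by a run-based union–find pass; components
are summarised (pixel count, exact fractional centroid, bounding box,
border contact) and ordered largest-first with deterministic tie-breaks.
The tip is the **centroid** of the selected component: tip masks are small
blobs and the centroid is rotation-stable, unlike an extremal pixel. When
several catheters are in the field, the component metrically closest to the
reference landmark is assessed; without a landmark, the largest.

The NGT has no tip channel, so its tip is recovered from the line skeleton:
Zhang–Suen thinning (followed by a staircase-corner pruning pass) reduces
the line to an 8-connected chain; the skeleton point nearest the carina
anchors the proximal end, and the tip is the point farthest from it by arc
length. Without a carina the lowermost end is used and the fallback is
flagged. Arc lengths — including the advancement beyond the GE junction and
the visible line length — are geodesic distances through the skeleton's
8-adjacency graph, axial steps weighing one pixel spacing and diagonal
steps `sqrt(spacingRow^2 + spacingCol^2)`. On rasterized straight segments
of 40–150 px this measures within 8% of the analytic length at any angle
(the worst case sits near 22.5°, where any 8-connected chain overestimates);
the category bands the generator samples keep more margin than that. One
asymmetry is deliberate: a *component's* border contact uses an exact 0 px
margin, but the *derived* NGT tip counts as on-border within 3 px, because
thinning erodes skeleton endpoints by up to the line half-thickness.

## Evaluation harness

Per-label AUCs are one-vs-rest Mann–Whitney probabilities (ties count ½,
computed from average ranks). Group AUCs are unweighted means over the
group's defined labels. Confidence intervals are percentile bootstrap
(2.5/97.5) over 1000 resamples of *images* — the resampling unit is the
radiograph — with the group average bootstrapped as a statistic of its own,
not assembled from per-label intervals. Resampling is stratified on the
ground-truth category so rare categories cannot vanish from a resample;
resamples on which a metric is still undefined are redrawn (bounded at ten
times the bootstrap count). A label with single-class ground truth has an
*undefined* AUC: it is reported as an explicit `"undefined"` cell, and it
propagates as an error when a caller asks for it directly.

Landmark accuracy is the per-image Euclidean distance in mm between
predicted and reference coordinates, summarised as mean and SD (population
SD by convention, switchable); paired conditions are compared with a
two-sided paired t-test. A comparison is flagged significant only when
p < 0.05 *and* the two 95% intervals do not overlap. Subgroup reports (for
example radiographs with and without ECG leads) recompute the full table
independently per stratum, reporting undefined cells rather than dropping
strata.

## Sample-size calculation

The design question "how many cases to show an AUC of 0.9 against a null of
0.7?" is answered with the Hanley–McNeil variance
$V(A) = \frac{A(1-A) + (n_+-1)(Q_1-A^2) + (n_--1)(Q_2-A^2)}{n_+ n_-}$,
$Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$, and the normal-approximation power
$\Phi\!\big((A_1 - A_0 - z_{1-\alpha/2}\sqrt{V_0})/\sqrt{V_1}\big)$.
The search returns the smallest positive-group size whose achieved power
reaches the target, with the negative group tied to it by the prevalence
(ratio 19 at 5%); positives are effectively ceiled and the search is
verified against an exhaustive scan in the tests. At the defaults
(0.9 vs 0.7, two-sided α = 0.05, power 0.8, 5% prevalence) the minimum
design is 15 + 285 = 300 cases:

```{r}
aucSampleSize(0.9, 0.7, alpha = 0.05, power = 0.8, prevalence = 0.05)
```

## The synthetic generator

`SimConfig()` describes a cohort shaped like a 303-patient adult ICU
population: tube presence ETT 178/303, CVC 148/303, NGT 39/303; category
mixtures ETT 140/33/5, CVC 98/27/12 (+11 Swan-Ganz), NGT 20/4/2/13; ECG
leads on 151/303. These mixtures are the generator's defaults, not dials.
Per image it samples

* **anatomy**: carina in a central upper band, cavoatrial junction 3–5.5 cm
  right and 4–6.5 cm below it, GE junction in the lower region — all
  strictly in-bounds, carina always cranial to the cavoatrial junction;
* **tubes**: smooth polylines from an entry edge to a tip whose distance
  realizes the requested category, sampled a few millimetres inside the
  band edges so rasterization and skeleton measurement cannot flip the
  category (ETT Normal draws 37–68 mm against the 35–70 band, NGT
  Borderline 8–88 mm against 0–100, and so on). The NGT descends past the
  carina column, through the GE junction, then curls on an 85 px radius —
  large enough that even a fully advanced tip stays caudal to the junction;
  the incompletely-imaged case is a short segment running off the bottom
  edge;
* **masks**: lines stamped at 3 px thickness, tips as 3 px-radius discs
  (there is no ETT line channel and no NGT tip channel, mirroring the
  channel scheme);
* **scores**: binormal — the true label's latent score is
  `Normal(sqrt(2) * qnorm(targetAuc), 1)`, competitors `Normal(0, 1)`, both
  squashed through the logistic, which leaves rank-based AUCs untouched;
* **reader noise**: isotropic Gaussian landmark displacement with a per-axis
  SD in mm (default 3 mm, a few-millimetre scale typical of human carina
  labelling), whose MAE converges to the Rayleigh mean `sd * sqrt(pi/2)`.

Defaults are 512 × 512 px at 0.7 mm/px — a ~36 cm field typical of
downsampled portable radiographs. One base seed drives everything; each
image derives its own substream by counter, so extending the cohort does
not perturb earlier images, and identical seeds reproduce byte-identical
mask, landmark and report files.

What the generator does **not** emulate: image texture and photorealism
(only masks, landmarks and scores exist), segmentation failure modes
(fragmented or missing masks beyond what rasterization produces),
ECG leads as pixels (the subgroup flag is sampled, not rendered), multiple
simultaneous catheters, or correlated classifier errors. Passing tests
therefore demonstrate that the geometry, rules and statistics are correct
on well-formed inputs; they do not certify any particular segmentation
network.

## Problem sizes in the test suite

The suite exercises the oracles at sizes chosen to keep the full run in the
low minutes on one core while leaving the statistics meaningful: 1000
random masks up to 64 × 64 against a flood-fill labelling oracle, 1000
random score vectors against an all-pairs AUC oracle, 200 bootstrap
replications (1000 resamples each, n = 500) for CI coverage, 2000 noisy
landmarks for the Rayleigh recovery, and 1000 synthetic tube instances for
the generate → rasterize → extract → classify round trip, which must
recover the requested category at least 99% of the time. The directional
property that enabling the rule-based correction raises the ETT group AUC
is checked on a 303-image cohort generated at a target AUC of 0.7, where
geometry has headroom to help.

## Known limitations

* CVC assessment from tip position alone is intentionally partial; the
  angle/kink/aberrant-vessel criteria need vessel segmentation.
* The NGT "within the tracheobronchopulmonary system" abnormality is not
  geometrically determined; only upstream classifier scores can express it.
* The right-atrium band and the NGT-tip fallback definition are documented
  engineering conventions, not measured anatomy.
* The DICOM reader handles explicit-VR little-endian files and only the
  pixel-spacing attributes; it is a metadata scanner, not a DICOM
  implementation.
* Skeleton arc length inherits the intrinsic ~8% worst-case overestimate of
  8-connected chains at oblique angles; thresholds that matter (the 10 cm
  NGT rule) are applied to measurements with generator margins wider than
  that, and real deployments should prefer tips from dedicated tip channels
  wherever they exist.
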