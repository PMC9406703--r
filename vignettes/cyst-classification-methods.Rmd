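---
title: "Spatial-context classification of jaw cysts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial-context classification of jaw cysts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cystdx)
```

## The diagnostic problem

Cystic lesions of the jaw appear on panoramic radiographs (OPGs) as
radiolucencies, and a clinician's preliminary classification leans heavily on
spatial context: a cyst whose cavity contains a tooth apex is almost certainly
of dental (odontogenic) origin, while a radiolucency with no discernible
causative dental pathology nearby is non-odontogenic. `cystdx` implements this
reasoning as a pipeline: a lesion detector proposes a bounding box, anatomy
segmentation supplies one binary mask per structure, the box/mask overlaps
become a feature vector, and a Random Forest issues the class call.

The package's computational contribution is everything downstream of the
neural networks: the overlap features, the forest, and the full evaluation
protocol. Networks themselves are out of scope; their *output contracts* —
boxes with confidence scores, masks with a given Dice quality — are emulated
by a seeded simulator so that every stage is testable without patient data.

## The overlap feature vector

For a bounding box $B$ and a binary mask $M$ on the same pixel grid, the
overlap share is

$$s(B, M) = \frac{|\{p \in B : M(p) = 1\}|}{|B|} \in [0, 1],$$

the fraction of the box covered by the structure. Pixels are counted under a
0-based, half-open box convention (a box at $(x, y)$ with width $w$ covers
columns $[x, x+w)$), which removes every off-by-one ambiguity: `iou()`,
`overlap_share()` and `dice()` agree exactly with brute-force pixel
enumeration, and the test suite asserts this on a thousand random instances.

One sample yields 37 features in a fixed order: `maxilla`, `mandible`,
`mandibular_canal`, `maxillary_sinus`, `dentition`, then the 32 permanent
tooth positions in FDI order (`tooth_11` … `tooth_48`). Design choices worth
stating:

* **Fixed 32-slot tooth block.** Classifiers need fixed dimensionality, so
  absent teeth contribute a structural zero rather than shrinking the vector.
* **Left/right merging.** The two mandibular canals and two maxillary sinuses
  are merged into one mask each, matching the single per-structure feature.
* **Dentition is the union of the teeth.** Consequently the dentition share
  always dominates every individual tooth share (up to independent
  segmentation noise), and — importantly for interpretation — it is a
  *sufficient statistic* for the class signal the simulator plants. Feature
  importance must therefore be read at the level of the dental block (teeth
  plus dentition); permuting the teeth alone cannot remove the dental signal
  because dentition still carries it.
* **Boxes are clipped to the image** before overlap computation, since
  jittered detections may leave the frame; the clipped pixel area is the
  denominator.
* **Empty-vs-empty Dice is defined as 1**: predicting absence of a truly
  absent structure is a perfect answer.

## The Random Forest

The classifier is a from-scratch bagged forest of CART trees:

* each tree grows on a bootstrap resample of size $n$ (drawn with
  replacement);
* at every split, `m_try` candidate features are drawn uniformly without
  replacement; the default `m_try = floor(sqrt(37)) = 6` is the standard
  heuristic;
* splits minimise weighted Gini impurity $1 - \sum_c p_c^2$, with candidate
  thresholds at midpoints between consecutive distinct feature values —
  deterministic, no random threshold sampling;
* ties are broken by lowest feature index, then lowest threshold, so a fitted
  forest is a pure function of `(X, y, params, seed)`;
* prediction is a majority vote; an exact tie goes to the odontogenic class,
  the majority class in clinical samples (configurable by reordering
  `cyst_classes()` is deliberately *not* offered — the tie rule is part of
  the documented contract);
* a single tree with `m_try` equal to the feature count and no depth limit
  reproduces exhaustive greedy CART exactly, which the tests verify against
  an independent brute-force implementation.

Hyperparameter tuning uses a grid search over
`n_trees {100, 500, 1000} x m_try {3, 6, 12} x min_samples_split {2, 5}`
scored by 5-fold cross-validated macro-F1 with fold assignment fixed by the
seed. The published pipeline names only the winning ensemble size (1000
trees) and the Gini criterion; the grid and the CV objective are this
package's own concrete choices, stated here so they are reproducible rather
than implied.

Evaluation follows the 80/20 protocol: a stratified split (training size
`round(0.8 n)` exactly), training on annotated-box features, and prediction
on both branches — annotated boxes and detected boxes. Because a detected box
only exists above a confidence threshold, the detected branch suffers sample
attrition as the threshold rises; `threshold_sweep()` reports the retained
count and per-class metrics per threshold, and the retained count is
non-increasing by construction.

## Detection and rating metrics

Detection evaluation is COCO-style: greedy matching of confidence-ranked
detections to ground truths at an IoU threshold (each ground truth matched at
most once, at most 100 detections per image), 101-point interpolated average
precision, and AP/AR averaged over IoU 0.50–0.95 in steps of 0.05. The
101-point interpolation is an explicit assumption: headline numbers in this
field are reported in the COCO convention without naming the interpolation,
and the all-cutoffs brute force in the test suite pins the implementation
exactly on every small instance.

Diagnostic metrics (sensitivity, specificity, PPV, NPV, F1) are computed
one-vs-rest from confusion counts. Cells with zero denominators are flagged
`NA`, never silently reported as 0. For a two-class problem the per-class
columns obey an exact exchange symmetry — sens(A) = spec(B), PPV(A) = NPV(B)
— which the tests assert on hundreds of random prediction sets; it is a
useful arithmetic cross-check on any published two-class table.

Inter-rater agreement uses Fleiss' kappa with subjects-by-categories vote
counts. When every vote falls in a single category the chance agreement is
total and kappa is undefined; the implementation flags this (`NA` with a
warning) rather than returning a number. The confidence interval is a
percentile bootstrap over subjects (2000 resamples by default) — the CI
method for the published kappa is unstated, so the package documents its own.

## The scene simulator

`generate_scene()` draws a stylised 2-D panoramic projection: maxilla and
mandible as horizontal bands, 16 tooth slots per arch with tapered roots,
two canal bands inside the mandible, two elliptical sinuses in the maxilla.
Only the *overlap topology* of these structures matters downstream — no
claim of radiographic realism is made and none is needed, because every
consumer of a scene sees only binary masks and boxes.

Class definitions are operationalised as placement rules:

* **odontogenic** — box centred near the apex of a uniformly chosen present
  tooth, with at least 10% of its area over that tooth's mask;
* **non-odontogenic** — box rejection-sampled inside jaw bone or sinus with
  zero overlap with every tooth mask.

This plants an exactly recoverable rule (odontogenic ⇔ any tooth feature
positive) that anchors the test suite: on noise-free scenes the rule
classifies perfectly, so any held-out error is attributable to the finite
forest, and the parameter-recovery test demands sensitivity and specificity
of at least 0.95 for both classes at $n = 500$.

Imperfection is injected through explicit, separately seeded channels:

* **Detector** — each lesion is missed with probability `fn_rate` (default
  0.1); surviving boxes get Gaussian corner jitter (`jitter_sd = 3` px) and a
  confidence from Beta(5, 2). False positives appear at rate `fp_rate`
  (default 0.1, at most 2 per image) with confidence Beta(2, 4). The FP boxes
  are radiolucency mimics: half are centred near a random tooth apex, half
  fall anywhere in the jaw bands. The confidence distributions overlap
  deliberately — a moderate-precision detector sometimes ranks a false
  positive above the true lesion, and that mislocalised top box is what makes
  the detected-branch classification imperfect in the way real pipelines are.
  Because the odontogenic class is the majority (72/28 default mix), such
  errors depress the minority-class F1 more, which is why the detected branch
  shows odontogenic F1 above non-odontogenic F1 under default noise.
* **Segmenter** — `degrade_mask()` lowers a mask to a target Dice $d$ by
  removing $k = \mathrm{round}(a(1-d))$ random foreground pixels and adding
  $k$ pixels from successive border rings, so the achieved Dice is exactly
  $1 - k/a$ up to rounding — well inside the ±0.05 contract by construction,
  with no iteration or calibration loop. Default targets are the published
  per-structure segmentation levels: dentition 0.945, mandible 0.978,
  mandibular canal 0.794, maxillary sinus 0.644, maxilla 0.465, individual
  teeth 0.870.

What the simulator does *not* emulate — and hence what passing tests do not
show about clinical data: image intensities (there are none), anatomical
shape variation beyond tooth presence/absence, mixed or pediatric dentition,
multi-lesion interaction, and above all the *intrinsic class ambiguity* of
real cysts. The planted rule makes the two classes geometrically separable by
design, so annotated-branch metrics near 1.0 here say nothing about the much
harder clinical separation; only the *relative* behaviour of the branches and
the direction of class asymmetry transfer as qualitative claims.

## Numerical choices and degenerate inputs

* Box width/height must be strictly positive; annotation parsing rejects
  violations with the offending line number.
* `overlap_share` on a box entirely outside the image is an error, not 0.
* `gini` on an empty count vector, Dice on mismatched dimensions, forests on
  single-class labels, and AP with zero ground truths are all errors.
* Degraded masks of empty structures (absent teeth) are left empty.
* All generators restore the caller's RNG state; every function that draws
  randomness takes an explicit seed, and derived per-scene seeds stay below
  $2^{31}$.
* Sample sizes used by the shipped tests and the acceptance script (500
  noise-free scenes for rule recovery; 120–150 scenes per noisy pipeline
  run; 1000 trees for recovery, 200–500 elsewhere) are the package's chosen
  study sizes: large enough that the asserted properties are stable across
  seeds, small enough to keep a full run on one CPU in minutes.

## Known limitations

* The anatomy cartoon has no shape variability; tooth presence is the only
  anatomical degree of freedom.
* The negative (cyst-free) scene stream feeds only the detection-stage
  evaluation; classification consumes lesional samples, mirroring a protocol
  in which negatives cannot enter the two-class stage.
* Forest probabilities are raw vote fractions; no calibration is attempted.
* The bootstrap CI for kappa resamples subjects only; rater-level variance
  is not modelled.

## A worked end-to-end run

```{r example, eval = FALSE}
cfg <- experiment_config(n_scenes = 120, prop_positive = 0.9, seed = 1,
                         forest = forest_params(n_trees = 500),
                         outdir = "cystdx_run")
res <- run_experiment(cfg)
res$detection_metrics
res$sweep[, c("threshold", "n_samples_retained",
              "odontogenic_f1", "non_odontogenic_f1")]
round(res$dice_report[1:5], 3)
```

The run directory then contains the plain-text annotation file, COCO-style
ground-truth and detection JSON, both feature CSVs, the serialized forest,
detection metrics, both classification reports, the per-structure Dice table
and a manifest whose seeds fully determine every output byte.
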