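Package: cystdx
Title: Spatial-Context Classification of Jaw Cysts on Panoramic Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for emulating the clinical diagnostic reasoning used to give
    jaw cysts a preliminary radiological classification. A detected lesion's
    bounding box is overlaid on segmentation masks of neighbouring anatomical
    structures (maxilla, mandible, mandibular canals, maxillary sinuses,
    dentition and 32 individual teeth); the per-structure overlap shares form a
    37-dimensional feature vector that a bagged Random Forest with Gini splits
    classifies into odontogenic versus non-odontogenic cysts. The package
    includes a seeded synthetic jaw-scene simulator (anatomy masks, lesion
    placement, imperfect detections and degraded segmentations), COCO-style
    detection evaluation (average precision and recall over IoU ranges),
    confidence-threshold sweeps with sample attrition, diagnostic test metrics
    (sensitivity, specificity, PPV, NPV, F1) and inter-rater agreement via
    Fleiss' kappa with a bootstrap confidence interval.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
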