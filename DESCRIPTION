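Package: sinusplan
Title: Landmark-Guided Surgical Planning for Maxillary Sinus Floor
    Augmentation from CBCT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage analysis of cone-beam computed tomography (CBCT)
    volumes of the posterior maxilla for implant treatment planning: a
    cascaded coarse-to-fine volumetric heatmap-regression network detects
    five anatomical landmarks (alveolar crest, sinus floor, medial and
    lateral ridge points, adjacent cementoenamel junction), and a
    distance-prior-guided 3D classification network maps the volume, the
    predicted heatmaps and three inter-landmark distances to one of five
    surgical approaches of a modified ABC sinus-augmentation
    classification.  Includes a synthetic CBCT phantom generator with
    analytically known landmarks and rule-derived class labels, a
    deterministic implementation of the modified ABC rules, and the
    evaluation statistics of the field (mean radial error, successful
    detection rates, per-class accuracy/sensitivity/specificity, ROC AUC,
    majority-vote ground truth, and Fleiss kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
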