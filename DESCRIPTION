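Package: plexuq
Title: Uncertainty Quantification for Ensemble Choroid Plexus Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for probabilistic evaluation of 3D medical image
    segmentation with Monte Carlo dropout and model ensembles. Generates
    stochastic probability stacks from a pluggable predictor, computes
    voxel-wise uncertainty maps (total predictive entropy, expected
    per-sample entropy, mutual information/BALD, predictive standard
    deviation), aggregates mask-restricted per-subject uncertainty,
    builds consensus segmentations, scores them against ground truth
    (Dice, Hausdorff, volume similarity, volume correlation), and
    compares uncertainty across cohorts with Welch tests, FDR correction
    and out-of-distribution flagging. A synthetic phantom module with a
    parametric stochastic predictor and a small trainable dropout
    classifier makes the whole pipeline testable without imaging data.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
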