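Package: rgcest
Title: Structure-Function Estimation of Retinal Ganglion Cell Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates retinal ganglion cell (RGC) counts in early glaucoma
    from structural and functional measurements. Implements the combined
    structure-function index (CSFI), which weights perimetry-derived and
    OCT-derived RGC counts by visual-field mean deviation; linear
    mixed-model estimators that predict CSFI counts from age, average
    retinal nerve fiber layer thickness and steady-state pattern
    electroretinogram amplitudes, with random-split cross-validation;
    cohort-level inference (one-way ANOVA with eta-squared, Games-Howell
    post hoc comparisons, Welch t-tests, Pearson correlation, ROC
    analysis); and a synthetic bilateral-cohort simulator with
    within-subject inter-eye correlation for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
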