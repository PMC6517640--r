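Package: gpdecode
Title: Gaussian Process Decoding of Clinical Scores from Brain Contrast Maps
Version: 0.1.0
Authors@R: person("gpdecode", "Maintainers", role = c("aut", "cre"),
    email = "maintainers@example.org")
Description: A whole-brain multivoxel pattern-regression pipeline that predicts
    continuous anxiety and depression scores (STAI-T, STAI-S, MASQ-D, HAM-A,
    HDRS) from per-subject fMRI contrast maps. Implements Gaussian-process
    regression and classification with a linear kernel, scanner-balanced
    cross-validation with fold distribution checks, confound removal estimated
    on training folds only, permutation inference on Pearson r and normalized
    mean squared error, dual-to-primal weight-map reconstruction, and
    atlas-based region localization of the predictive pattern. Ships a
    synthetic-cohort generator that reproduces the statistical structure the
    analysis assumes (per-group score distributions, zero-inflated clinician
    scales, unbalanced scanner splits, frontal signal-dropout patches, and a
    low-SNR spatially distributed score-linked signal), so the full pipeline is
    exercisable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
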