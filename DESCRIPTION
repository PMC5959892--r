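Package: reims
Title: Tissue Recognition from Rapid Evaporative Ionisation Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for building and validating intra-operative tissue
    recognition models from rapid evaporative ionisation mass spectrometry
    (REIMS, "iKnife") peak lists. Covers synthetic cohort simulation with
    known ground truth, lock-mass recalibration, background subtraction and
    0.1 Da spectral binning, principal-component linear-discriminant (PC-LDA)
    classification with posterior-probability thresholding,
    leave-one-patient-out cross-validation with sample-level majority voting,
    univariate discriminatory-peak discovery with Benjamini-Yekutieli false
    discovery rate control, Cohen's kappa inter-rater agreement, and in-silico
    negative-mode glycerophospholipid ion annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    mzR,
    MASS,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
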