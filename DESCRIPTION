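Package: semspace
Title: Principal Preserved Components Analysis of Cross-Cultural Emotion Ratings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how emotional experience and its facial
    expression are shared across groups of raters. Implements principal
    preserved components analysis (PPCA), the eigendecomposition of the
    symmetrized cross-covariance between two parallel rating datasets, with
    leave-one-rater-out significance testing of each dimension (partial
    Spearman correlations, one-tailed Wilcoxon signed-rank tests, and the
    ForwardStop sequential FDR stopping rule), varimax rotation of the
    significant components, interrater-reliability noise ceilings and
    attenuation-adjusted correlations, Spearman-Brown style explainable
    variance of averaged responses, leave-one-stimulus-out linear prediction
    of experience from expression features within and across groups,
    cross-group target calibration, within-group intensity normalization,
    and a synthetic two-culture rating and expression generator with known
    latent structure for validating every stage against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
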