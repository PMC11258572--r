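Package: natriq
Title: Quantitative Sodium MRI Simulation, Partial-Volume Regression and
    Longitudinal Outcome Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative sodium (23Na) brain MRI at the image and
    cohort level. Simulates digital sodium phantoms with known ground truth
    (tissue-fraction maps, T2-driven point-spread-function blurring, Rician
    noise), calibrates raw signal to millimolar concentration against a
    background-noise and vitreous-humour internal reference, estimates global
    grey- and white-matter apparent total sodium concentration (aTSC) by
    partial-volume linear regression, scores the RPQ, BTACT and GOSE clinical
    outcome instruments, and runs a six-hypothesis nonparametric battery
    (Mann-Whitney U, matched-pair Wilcoxon signed-rank, Spearman correlation
    with exact permutation p-values, Cohen's d) for longitudinal
    concussion-outcome studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
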