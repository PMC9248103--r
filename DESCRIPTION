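Package: frailvoice
Title: Vocal Biomarkers of Frailty from Sustained-Vowel Acoustics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates sustained-vowel /a/ recordings and synthetic geriatric
    cohorts with a configurable frailty-voice effect structure, extracts four
    acoustic parameters (zero-crossing rate, peak/valley amplitude variation,
    first/second formant variation via linear prediction, and the spectral
    energy ratio above 3 kHz), scores frailty by the CHS (Fried phenotype),
    SOF and FRAIL indices, and estimates feature-frailty associations with
    univariate logistic regression reported as odds ratios with Wald 95%
    confidence intervals, including sex-stratified models, descriptive
    cohort tables and probability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
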