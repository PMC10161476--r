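Package: hrvbeta
Title: Heart Rate Variability, OGTT Beta-Cell Response and Synthetic
    Cohort Association Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking 24-hour cardiac autonomic function, measured as
    time- and frequency-domain heart rate variability (HRV) from labelled
    beat series, to beta-cell response during a seven-point oral glucose
    tolerance test (OGTT). Implements NN-interval extraction with non-sinus
    exclusion, the standard Task-Force time-domain indices (SDNN, SDANN,
    RMSSD, SDNN index, NN50, pNN50, SDSD) and FFT band powers (TP, ULF, VLF,
    LF, HF), composite z-scores; a C-peptide based beta-cell secretion model
    (linear dose-response with glucose sensitivity, rate sensitivity on
    rising glucose, and a time-varying potentiation factor) fitted through
    two-compartment C-peptide kinetics, plus formula-based indices
    (C-peptidogenic index, AUC ratio, Matsuda index); a standardized-beta
    covariate-adjustment regression ladder with interaction, stratified and
    tertile-logistic analyses; and a calibrated structural-equation
    synthetic cohort generator with score-level and signal-level modes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
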