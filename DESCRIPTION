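Package: qeegprog
Title: Quantitative EEG Features and Prognostic Modelling for Post-Cardiac-Arrest Coma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end quantitative EEG analysis for neurological prognosis of
    comatose patients after cardiac arrest. Reads WFDB-style continuous EEG with
    clinical metadata sidecars, standardises recordings to the 19-channel 10-20
    montage (band-pass 0.5-45 Hz, 256 Hz, average reference), rejects artifact
    epochs by peak-to-peak amplitude, and extracts three hourly feature families:
    Welch band power (delta/theta/alpha/beta/gamma), magnitude-squared coherence
    over all 171 channel pairs, and burst suppression ratio at 5/10/15 uV
    thresholds. Features are aggregated over four post-ROSC periods into a named
    4028-dimensional vector, fed through a feature-selector x classifier grid
    (L1-linear, random-forest and gradient-boosting selectors; seven classifier
    families) with stratified five-fold and leave-one-hospital-out
    cross-validation, scored by the true-positive rate at a false-positive rate
    capped at 0.05 alongside AUROC, AUPRC and F1, and interpreted with additive
    (SHAP) attributions aggregated by electrode distance, frequency class and
    time period. A synthetic-cohort generator with planted band powers, coherent
    sources, burst-suppression occupancy and artifacts provides ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    glmnet,
    ranger,
    xgboost,
    e1071,
    class
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
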