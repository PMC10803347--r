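Package: sepsislab
Title: Sepsis-III Onset Labeling and Real-Time Sepsis Prediction Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the onset of sepsis from intensive-care
    electronic health records under the sepsis-III consensus definition, and
    for training and evaluating hourly real-time sepsis risk models against
    competing onset interpretations. Implements antibiotic-course detection
    and antibiotic/blood-culture proximity pairing to locate suspected
    infection, hourly six-component SOFA scoring on a forward-filled grid with
    windowed deterioration detection, three competing onset definitions
    (organ-dysfunction time, suspicion time, and their minimum), cohort
    exclusion rules and stratified train/test splitting, patient-hour feature
    matrices with rolling-window and path-signature features, three
    interchangeable risk scorers (gradient-boosted trees, a small LSTM, and a
    horizon-risk proportional-hazards model), and patient-hour AUROC
    evaluation with patient-level bootstrap confidence intervals. A synthetic
    ICU cohort generator with known ground-truth infection timings makes the
    whole pipeline testable without access to credentialed clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    survival,
    xgboost,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    arrow
Config/testthat/edition: 3
RoxygenNote: 7.3.3
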