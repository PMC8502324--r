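Package: losnet
Title: Length-of-Stay Prediction, Interpretation and Bed-Day Impact for
    Hospital Departments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts hospitalizations that exceed national DRG length-of-stay
    benchmarks or outlier thresholds with a single-hidden-layer feed-forward
    neural network trained by back-propagation and selected through a
    sensitivity/specificity-constrained bootstrap.  Trained networks are
    interpreted with Garson percentage contributions and synaptic-weight signs,
    and the bed-days freed by efficient interventions on predicted positives
    are converted into additional hospitalizations and reimbursement revenue.
    Includes a synthetic admission-cohort generator with configurable covariate
    prevalences and a planted covariate-effect model on log length of stay, a
    diagnostic evaluation report (sensitivity, specificity, likelihood ratios,
    AUC with Wald intervals), and an end-to-end train-on-year-one /
    simulate-on-year-two pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
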