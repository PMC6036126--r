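Package: ApneaScreen
Title: Phenotype-Based Inter-Individual Sleep Apnea Screening from
    Respiratory Effort and Oximetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Screens for sleep apnea from a minimal (Level IV-like) montage
    of thoracic and abdominal respiratory-effort accelerometry and pulse
    oximetry. For each new subject a neighbor-specific classifier is trained
    on the most phenotypically similar subjects of an annotated cohort,
    selected by a weighted gender/age/BMI metric with a comorbidity
    correction distance (a modified k-nearest-neighbor scheme). Epoch
    features (breathing-envelope amplitude, dominant breathing frequency,
    thoraco-abdominal paradox, and oxygen-desaturation statistics) feed an
    RBF-kernel support vector machine whose output is smoothed by a state
    machine and corrected by desaturation detection; epoch labels become
    timed events, a respiratory event index (REI), and a four-level severity
    grade. Includes the leave-one-subject-out evaluation protocol
    (event-by-event matching, confusion matrices, screening likelihood
    ratios) and a synthetic cohort simulator with planted events so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    e1071,
    jsonlite,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
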