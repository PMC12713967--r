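Package: rrdip
Title: Detection of Respiratory-Related Heart-Rate Changes from
    RR-Interval and Pulse-Rate Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automated detection of transient heart-rate accelerations
    (RR-interval dips) in beat-to-beat tachograms derived from single-lead
    ECG, and of the analogous accelerations in 1-Hz pulse-rate recordings,
    for screening of sleep-disordered breathing. Detected dips are linked
    to pre-scored respiratory events and arousals to form per-study
    severity indices (total and respiratory-related RR-dip and
    heart-rate-acceleration indices, events per hour of recording).
    Includes readers and writers for interval/pulse CSV, EDF signals and
    NSRR-style annotation XML, a synthetic sleep-study generator with
    known ground truth, and the agreement and diagnostic statistics used
    to validate heart-rate indices against the polysomnographic
    apnea-hypopnea index (confusion matrices, sensitivity/specificity,
    Cohen's kappa, intraclass correlation, Bland-Altman limits, ROC/AUC,
    covariate-adjusted correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
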