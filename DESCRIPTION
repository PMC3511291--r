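Package: lungrecruit
Title: Error-Function Recruitment Modelling of Step-Wise PEEP Manoeuvres
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of step-wise PEEP recruitment manoeuvres with a minimal
    pulmonary recruitment model. Ventilator pressure/flow waveforms are
    segmented into breaths and turned into per-PEEP pressure-volume curves
    (including the trapped-volume offset at each PEEP increment); each limb is
    fitted with an error-function model of normally distributed threshold
    opening/closing pressures (TOP/TCP) to estimate the mean, SD and
    recruitable capacity; fits are summarised into median/IQR tables, compared
    with Wilcoxon rank-sum tests, and placed on the disease-state-grouping
    (TOP vs SD) plane. A multi-compartment lung simulator with hysteretic
    opening/closing units generates synthetic manoeuvre waveforms with known
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
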