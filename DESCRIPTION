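Package: coughval
Title: Evaluation of Continuous Cough Monitors Against a Multi-Annotator
    Gold Standard
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to validate automated cough-detection devices against
    continuous audio recordings annotated by multiple human listeners.
    Reads annotation label tracks and detector event logs, estimates
    per-device clock offsets by grid search, builds a per-second gold
    standard from three-annotator tier consensus, computes pooled and
    per-session sensitivity and specificity with exact Clopper-Pearson
    intervals, and assesses minute-level cough-rate agreement via Pearson
    correlation, linear fits and Bland-Altman percentage error. Includes
    a solicited-sound session simulator with configurable detector and
    annotator noise, plus study-design utilities (scripted sound
    sequences and Buderer-style diagnostic sample sizes).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
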