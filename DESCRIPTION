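Package: randelphi
Title: Consensus Analysis for Multi-Round RAND/UCLA Appropriateness Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing multi-round expert-panel (Delphi) rating
    studies with the RAND/UCLA appropriateness method: per-item medians and
    30th/70th percentiles on the 1-9 rating scale, the disagreement index
    (interpercentile range divided by the interpercentile range adjusted for
    symmetry), agreement and appropriateness-band classification,
    round-to-round convergence and category cross-tabulation, report
    rendering in the field's customary table shapes, and a seeded synthetic
    panel generator for studying the operating characteristics of the
    consensus criteria. Includes the published round summaries of a
    two-round e-Delphi study of opioid prescribing-safety indicators as a
    worked example dataset.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
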