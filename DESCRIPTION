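Package: lvtps
Title: Left-Ventricle Surface Area from a Truncated Prolate Spheroid Model
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Closed-form surface areas for prolate spheroids, general
    ellipsoids and truncated prolate spheroids (TPS), and a geometric model
    of the human left ventricle (LV) that maps echocardiographic short-axis
    diameter and short/long-axis ratio to TPS semi-axes. Provides batch
    cohort analysis of sex- and age-stratified LV reference dimensions:
    surface-area tables, male/female percentage differences, comparison
    against a nuclear-imaging reference area, and small-sample Pearson
    correlation of surface area with normalized end-diastolic volume,
    together with a synthetic-cohort generator and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
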