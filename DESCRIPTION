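Package: grogscreen
Title: Validation Analyses for Short Alcohol Screening Tools Against the
    Last-Four-Occasions (Finnish) Method
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates alcohol consumption from the timing and quantity of a
    person's last four drinking occasions (the Finnish method), scores a
    colloquially worded AUDIT-C (AUDIT-Cm) and its item subsets, classifies
    short- and long-term drinking risk under the 2009 Australian NHMRC
    guidelines, and evaluates screening concordance (sensitivity and
    specificity with exact Clopper-Pearson confidence intervals) and the
    variance retained by shortened Finnish-method variants. Includes a
    seeded synthetic-cohort generator emulating intermittent, heavy
    per-occasion drinking so the full pipeline is testable without
    participant-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
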