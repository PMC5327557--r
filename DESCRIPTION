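Package: caseval
Title: Validation of Cancer Case Ascertainment Algorithms in Linked
    Administrative Health Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for ascertaining incident cancer cases from surrogate
    indicators (diagnosis, procedure, claims-item, pharmaceutical and
    cause-of-death codes) in linked administrative health datasets and for
    validating them against a gold-standard population cancer registry.
    Implements declarative ICD-10 code-list indicators with boolean
    combination algebra, month-precision temporal matching with a
    configurable window, diagnostic-accuracy metrics (sensitivity,
    specificity, positive predictive value) with Wilson score confidence
    intervals, lag profiling, mismatch characterisation, death-record
    discordance triage and incremental-case counting.  A synthetic
    linked-cohort generator with known ground truth and closed-form
    expected metrics supports parameter-recovery testing of the whole
    pipeline without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
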