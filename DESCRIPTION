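Package: autova
Title: Tariff-Based Verbal Autopsy Decision Support
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Assigns probable causes of out-of-facility deaths from verbal
    autopsy symptom endorsements using a tariff scoring engine, and presents
    the certifying physician with the top three candidate causes together
    with likelihood categories derived from percentile ranks against a
    resampled training reference, abstaining ("undetermined") when no cause
    clears the score and rank thresholds. Includes standard-operating-
    procedure routing of each death to certification from medical records,
    from the open narrative, or via the full verbal autopsy; evaluation of
    the resulting cause-of-death data (cause-specific mortality fractions,
    physician-algorithm agreement, reclassification matrices, ill-defined
    fractions, CSMF accuracy); and a synthetic-data module that generates
    training libraries, field cohorts with known true causes, and simulated
    physician behaviour so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
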