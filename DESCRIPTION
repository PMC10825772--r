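Package: oudseverity
Title: Infer Opioid Use Disorder Severity from Annotated Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for inferring opioid use disorder (OUD) severity
    from sentence-level annotations of clinical notes. Annotation classes
    are mapped to DSM-5 diagnostic criteria through a configurable
    "crosswalk"; each patient's endorsed-criterion count yields a severity
    score (0-11) and category (none/mild/moderate/severe). The package
    houses the hierarchical annotated-corpus data model with JSONL I/O,
    interannotator-agreement statistics with discordance reports for
    adjudication, severity-distribution and positive-predictive-value
    evaluation, documentation-pattern analytics (class frequencies by note
    type, encounter setting and encounter position; note yield; class-pair
    correlation and patient-level co-occurrence), and a seeded synthetic
    corpus generator with known per-patient ground truth for end-to-end
    validation without any real clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
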