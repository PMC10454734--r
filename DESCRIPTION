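Package: vbtr
Title: Value-Based Treatment Recommendation from Unified Clinical and Value Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for patient-centred therapy recommendation that combine
    guideline-derived clinical arguments with literature-derived value-based
    arguments in a single weighted evidence base. Provides a small condition
    language for eligibility rules, readers and writers for the tabular and
    RDF/Turtle argument formats, a keyword-driven literature screening
    pipeline with a seeded synthetic-corpus generator, occupation-based value
    pre-configuration with adaptive weight adjustment, and a recommendation
    engine that ranks treatment plans by a tunable blend of clinical and
    value scores, with per-argument explanations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
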