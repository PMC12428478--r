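Package: pmcindex
Title: Checklist-Based Policy Consistency Index Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative evaluation of policy document sets with a
    consistency-index model. Expert binary codings against a two-level
    variable hierarchy (primary dimensions decomposed into equal-weight
    yes/no indicators) are aggregated in exact rational arithmetic into
    per-dimension scores, a 0-9 consistency index, its indentation
    (concavity) complement, and grade classifications. Includes
    date-defined cohort comparison, a text-mining stage (term
    frequencies and sentence-window co-occurrence networks), surface and
    radar visualisations, synthetic-data generators with known ground
    truth, and a bundled worked evaluation of 28 care-integration
    policies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
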