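Package: aptscore
Title: Triangle-of-Biomedicine Content Scoring and Clinical-Citation Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies biomedical articles by their MeSH tree addresses into
    the Human, Animal, Molecular/Cellular, Disease, Therapeutic/Diagnostic and
    Chemical/Drug category systems, maps fractional HAMC content onto the
    triangle of biomedicine, builds 22-feature data profiles from articles and
    their time-truncated citing networks, trains and calibrates a random-forest
    classifier into five Approximate Potential to Translate (APT) bins, and
    measures the effect of counterfactual citation edits on APT scores. Ships a
    seeded synthetic literature-corpus generator with a planted clinical-citation
    mechanism so the whole pipeline is testable without bulk downloads, plus
    trilinear density-map rendering and a command-line workbench.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    pROC,
    ranger,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
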