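Package: amescade
Title: Cascaded SVM and Structural-Alert Prediction of Ames Mutagenicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid in silico classifier for bacterial (Ames) mutagenicity that
    couples a statistical C-SVC model on 25 molecular descriptors with a
    knowledge-based layer of structural alerts. Compounds predicted mutagenic by
    the support vector machine are accepted as such; predicted non-mutagens are
    re-screened by two consecutive structural-alert checkpoints ("enhancing" then
    "suspicious" alerts) selected by auditing a 30-rule mutagenicity rulebase
    against cross-validated predictions. The result is a three-way label
    (mutagenic / suspicious / non-mutagenic) with two user-selectable
    binarization policies trading accuracy against false-negative rate.
    Includes electrotopological-state, information-content, ring-count and
    atom-contribution logP descriptors, max-abs normalization, stratified
    splitting, three-output confusion matrices, and a deterministic synthetic
    molecule generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    bio3d,
    e1071,
    igraph,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
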