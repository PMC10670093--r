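Package: CytoBridge
Title: Screening Cytosolic Proteins that Bridge Mitochondria and the
    Endoplasmic Reticulum in Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Nominates cytosolic proteins that mediate cross-talk between
    mitochondria and the endoplasmic reticulum from a compartment-labelled
    protein-protein interaction network. Provides organelle catalog
    harmonization, MCODE-style dense-complex detection, Fisher-combined
    cross-study differential expression with DEG-to-cluster mapping,
    shortest-path bridging scores for cytosolic linker candidates, and
    delta-delta-Ct / one-way ANOVA / Tukey validation statistics, together
    with a seeded synthetic-data generator so every stage is testable
    offline against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
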