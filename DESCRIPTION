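Package: ezref
Title: Reference-Based Metabolic Potential Profiling of Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-enzyme reference probability distributions from a
    collection of metagenome enzyme-annotation count tables, scores query
    metagenomes with an equivalent z-score (EZS) that flags enzymes whose
    per-million annotation rates are atypical relative to the reference, and
    reconstructs the metabolic network implied by the non-depleted enzymes
    from KGML pathway files, clustering it with a Markov Cluster (MCL)
    implementation. Includes a synthetic-data module so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
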