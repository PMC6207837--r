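Package: nssanchor
Title: Resolve Non-Specific Structure Terms in Morphological Descriptions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resolving non-specific structure (NSS) terms -- anatomical
    part terms such as "apex", "base" or "margin" that do not denote an
    identifiable organ on their own -- to their anchor organs in annotated
    taxonomic morphological descriptions. Implements an ontology-constrained
    syntactic rule engine with recursive resolution of chained NSS terms, a
    pairwise support-vector-machine relation classifier with probability-based
    argmax anchor selection, two reference baselines (subject entity and closest
    entity), a micro-averaged precision/recall/F1 evaluation harness with
    pairwise error-overlap analysis, and a deterministic synthetic corpus
    generator that emits annotated statements together with matching soft
    part-of ontologies and gold anchors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
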