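Package: phenokg
Title: Instance-Based Phenotype Knowledge Graphs and Class-Based Semantic Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for representing empirical phenotype descriptions as semantic
    graphs, in two interconvertible forms: instance-based phenotype knowledge
    graphs (ABox), where every described part, quality, and measurement is an
    individual with its own URI organized along a parthood backbone, and
    class-based semantic phenotypes (TBox), where the description lives in the
    axiom of a phenotype class written in a Manchester-syntax subset built from
    Entity-Quality (EQ) statements. Descriptions can be fragmented into
    descriptive named graphs (one per smallest unit of empirical information),
    recomposed, filtered through data views, annotated with statement-level
    metadata, exported as nanopublications, and revised with full change
    tracking. A shape-template content standard, description-logics compliance
    checks for absence and exact-count constructs, and criteria-based querying
    over stores of descriptions are included, together with a deterministic
    synthetic-description generator and a small fixture vocabulary standing in
    for the UBERON, PATO, and MA ontologies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
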