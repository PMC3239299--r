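Package: ggprel
Title: Relation Ontology, Design Patterns and Finite-Model Checking for
    Gene/Gene-Product Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Formalizes the relation vocabulary used in GENIA-style biomedical
    corpus annotation: a taxonomy of individual-level (II-), class-level (CC-)
    and gene/gene-product-level (GGP-) relations with their mereological and
    variance axioms, two ontology design patterns that disambiguate relations
    whose argument is an ambiguous gene/gene-product (GGP) class, a converter
    from standoff annotation documents to OWL 2 ontologies (functional syntax
    and Turtle), and a closed-world finite-model checker that verifies
    annotations against the axioms and reports violations with witnesses,
    without requiring an external reasoner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
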