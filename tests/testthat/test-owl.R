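tax <- genia_taxonomy()

test_that("an empty axiom list yields a minimal valid ontology", {
  doc <- write_ontology(list())
  expect_match(doc, "Ontology\\(<http://example.org/ggprel/onto>")
  expect_match(doc, "Import\\(<")
  expect_match(doc, "Declaration\\(Class\\(:GGP\\)\\)")
  expect_length(parse_ontology(doc), 1L)  # the GGP declaration
})

test_that("non-simple properties lose restricted characteristics, recorded as comments", {
  ax <- list(
    ax_chain(c("II-part-of", "II-region-of"), "II-region-of"),
    ax_characteristic("II-region-of", "IRREFLEXIVE"),
    ax_characteristic("II-part-of", "TRANSITIVE"),
    ax_characteristic("II-part-of", "REFLEXIVE"),
    ax_characteristic("II-has-mutant", "SYMMETRIC"))
  doc <- write_ontology(ax)
  expect_false(grepl("IrreflexiveObjectProperty", doc))
  expect_false(grepl("ReflexiveObjectProperty", doc))
  expect_match(doc, "ggprel-omitted-characteristic: IRREFLEXIVE")
  expect_match(doc, "ggprel-omitted-characteristic: REFLEXIVE")
  # mutant is simple; its symmetry stays
  expect_match(doc, "SymmetricObjectProperty\\(:II-has-mutant\\)")
  expect_match(doc, "TransitiveObjectProperty\\(:II-part-of\\)")
})

test_that("no emitted document carries a restricted characteristic on a non-simple property", {
  wx <- worked_examples()
  for (nm in names(wx)) {
    ax <- convert_abstract(wx[[nm]]$annotation, tax)
    doc <- write_ontology(ax)
    ns <- nonsimple_properties(ax)
    for (r in ns) {
      pat <- paste0("(Reflexive|Irreflexive|Symmetric|Asymmetric)",
                    "ObjectProperty\\(:", r, "\\)")
      expect_false(grepl(pat, doc), info = paste(nm, r))
    }
  }
})

test_that("write then parse is identity modulo dropped characteristics", {
  wx <- worked_examples()
  for (nm in c("cd19-equiv", "cd19-promoter", "lck-src", "oct2-recombinant",
               "cd19-faulty")) {
    ax <- convert_abstract(wx[[nm]]$annotation, tax)
    back <- parse_ontology(write_ontology(ax))
    k1 <- sort(vapply(ax, axiom_str, ""))
    k2 <- sort(vapply(back, axiom_str, ""))
    extra <- setdiff(k2, k1)
    dropped <- setdiff(k1, k2)
    expect_true(length(extra) == 0L, info = paste(nm, extra[1L]))
    # everything dropped is a restricted characteristic on a non-simple rel
    ns <- nonsimple_properties(ax)
    for (d in dropped) {
      expect_match(d, "(Reflexive|Irreflexive|Symmetric|Asymmetric)ObjectProperty",
                   info = nm)
      expect_true(any(vapply(ns, function(r) grepl(r, d, fixed = TRUE), TRUE)),
                  info = d)
    }
    # a second pass is byte-identical (canonical form is a fixpoint)
    expect_identical(write_ontology(back), write_ontology(back))
  }
})

test_that("pattern axioms survive the round trip with their parameters", {
  ax <- expand_subclass_pattern(
    pattern_instance("G_CD19", "GGP-subclass-has-part", "CD19_promoter"),
    tax, provenance = "doc:R1")
  back <- parse_ontology(write_ontology(ax))
  pats <- Filter(function(a) a$type == "pattern", back)
  expect_length(pats, 1L)
  expect_identical(pats[[1L]]$pattern$name, "subclass-disjunction")
  expect_identical(pats[[1L]]$pattern$kinds, c("DNA", "RNA", "Protein"))
  expect_identical(pats[[1L]]$pattern$ggp, "G_CD19")
  expect_identical(pats[[1L]]$provenance, "doc:R1")
  expect_identical(axiom_str(pats[[1L]]), axiom_str(ax[[1L]]))
})

test_that("hand-written documents in the dialect parse; out-of-dialect input errors with position", {
  doc <- paste(
    "Prefix(:=<http://example.org/x#>)",
    "Ontology(<http://example.org/x>",
    "Declaration(Class(:A))",
    "SubClassOf(:A ObjectSomeValuesFrom(:r :B))",
    ")", sep = "\n")
  ax <- parse_ontology(doc)
  expect_length(ax, 2L)
  expect_identical(ax[[2L]]$type, "subclass")
  expect_identical(ax[[2L]]$sup$rel, "r")
  expect_error(parse_ontology("SubClassOf(:A"), "character")
  expect_error(parse_ontology("ObjectHasValue(:r :a)"), "out of dialect")
})

test_that("serialization is byte-deterministic", {
  wx <- worked_examples()
  ax <- convert_abstract(wx[["cd19-promoter"]]$annotation, tax)
  expect_identical(write_ontology(ax), write_ontology(ax))
  expect_identical(write_ontology(rev(ax)), write_ontology(ax))
  expect_identical(write_turtle(ax), write_turtle(ax))
})

test_that("Turtle output carries the same assertions in RDF form", {
  ax <- list(ax_declaration("class", "CD19"),
             ax_subclass("CD19", "Protein"),
             ax_chain(c("II-part-of", "II-region-of"), "II-region-of"),
             ax_characteristic("II-part-of", "TRANSITIVE"),
             ax_subclass("D", ce_some("II-has-mutant", ce_and("G", "Protein"))))
  ttl <- write_turtle(ax)
  expect_match(ttl, ":CD19 rdfs:subClassOf :Protein \\.")
  expect_match(ttl,
    ":II-region-of owl:propertyChainAxiom \\( :II-part-of :II-region-of \\)")
  expect_match(ttl, ":II-part-of a owl:TransitiveProperty")
  expect_match(ttl, "owl:onProperty :II-has-mutant")
  expect_match(ttl, "owl:intersectionOf \\( :G :Protein \\)")
})

test_that("stub imports keep conversion self-contained and the stub parses", {
  stub <- system.file("extdata", "so_genia_stub.ofn", package = "ggprel")
  ax <- parse_ontology(paste(readLines(stub), collapse = "\n"))
  ids <- unlist(lapply(ax, axiom_class_ids))
  expect_true(all(c("DNA", "RNA", "Protein") %in% ids))
  rels <- unlist(lapply(ax, axiom_rel_ids))
  expect_true(all(c("transcribed-from", "translated-from") %in% rels))
  cfg <- owl_config(stub = FALSE)
  doc <- write_ontology(list(), cfg)
  expect_match(doc, "purl.obolibrary.org/obo/so.owl", fixed = TRUE)
})
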