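tax <- genia_taxonomy()

test_that("worked examples cover the documented cases and parse cleanly", {
  wx <- worked_examples()
  expect_gte(length(wx), 10L)
  expect_true(all(c("cd19-equiv", "cd19-promoter", "cd19-locus",
                    "cd19-human", "hoxa1-family", "lck-src", "tr-alpha-1",
                    "acta1-isoform", "tnfri-mutant", "oct2-recombinant",
                    "il16-precursor", "gata3-antisense", "cd19-faulty")
                  %in% names(wx)))
  tags <- vapply(wx, function(e) e$tag, "")
  expect_identical(sum(tags == "inconsistent-under-generic-schema"), 1L)
  for (e in wx) {
    out <- write_annotation(e$annotation)
    b <- parse_annotation(out$txt, out$ann, doc_id = e$annotation$doc_id)
    expect_identical(b$terms, e$annotation$terms)
  }
})

test_that("every consistent worked example checks clean against its conversion", {
  wx <- worked_examples()
  for (nm in names(wx)) {
    e <- wx[[nm]]
    if (!identical(e$tag, "consistent")) next
    ax <- convert_abstract(e$annotation, tax)
    expect_identical(nrow(check(e$model, ax, tax)), 0L, info = nm)
  }
})

test_that("the fixture set exercises every relation in the taxonomy", {
  wx <- worked_examples()
  used <- character(0)
  pattern_rels <- character(0)
  for (e in wx) {
    schema <- if (identical(e$tag, "consistent")) "pattern" else "generic"
    ax <- convert_abstract(e$annotation, tax, schema = schema)
    used <- unique(c(used, unlist(lapply(ax, axiom_rel_ids))))
    for (a in ax) {
      if (a$type == "pattern" && !is.null(a$pattern$relation)) {
        pattern_rels <- c(pattern_rels, a$pattern$relation)
      }
      if (a$type == "subclass" && a$sup$kind == "some") {
        # variant expansions emit the II-level primitive; map it back to
        # the GGP relation defined from it
        prim <- a$sup$rel
        back <- names(tax$specs)[vapply(tax$specs, function(s)
          s$level == "GGP" && identical(s$defined_from, prim), TRUE)]
        pattern_rels <- c(pattern_rels, back)
      }
    }
  }
  expect_length(setdiff(names(tax$specs), used), 0L)
  # beyond declarations: every GGP-level relation is exercised by an
  # actual relation mention somewhere in the fixtures
  ggp_rels <- names(tax$specs)[vapply(tax$specs, function(s)
    s$level == "GGP", TRUE)]
  expect_length(setdiff(ggp_rels, unique(pattern_rels)), 0L)
})

test_that("uncorrupted corpora are violation-free; seeded runs are identical", {
  corpus <- random_corpus(20, 42, 0)
  expect_length(corpus, 20L)
  for (e in corpus) {
    expect_true(is.na(e$corruption))
    ax <- convert_abstract(e$annotation, tax)
    expect_identical(nrow(check(e$model, ax, tax)), 0L, info = e$doc_id)
  }
  corpus2 <- random_corpus(20, 42, 0)
  expect_identical(lapply(corpus, function(e) e$ann),
                   lapply(corpus2, function(e) e$ann))
  expect_error(random_corpus(3, 1, 1.5), "corruption_rate")
})

test_that("each corruption type is detected with its expected violation category", {
  corpus <- random_corpus(60, 8, 1)
  types_seen <- character(0)
  for (e in corpus) {
    types_seen <- c(types_seen, e$corruption)
    if (identical(e$expected_category, "parse-error")) {
      expect_error(parse_annotation(e$txt, e$ann), "dangling")
    } else {
      ax <- convert_abstract(e$annotation, tax)
      rep <- check(e$model, ax, tax)
      expect_true(e$expected_category %in% rep$category,
                  info = paste(e$doc_id, e$corruption))
    }
  }
  expect_setequal(unique(types_seen),
                  c("mutant-self-loop", "membership-cycle",
                    "kind-disjointness-clash", "dangling-arg"))
  # the targeted injection: a mutant self-loop yields specifically an
  # irreflexivity violation on the mutant relation
  loops <- Filter(function(e) identical(e$corruption, "mutant-self-loop"),
                  corpus)
  rep <- check(loops[[1L]]$model,
               convert_abstract(loops[[1L]]$annotation, tax), tax)
  hit <- rep[rep$category == "irreflexivity", ]
  expect_identical(unique(hit$subject), "II-has-mutant")
})
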