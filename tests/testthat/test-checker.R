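tax <- genia_taxonomy()

test_that("closure fires chains, transitivity and inverse rules", {
  ax <- c(location_chain_axioms(),
          list(ax_characteristic("II-part-of", "TRANSITIVE"),
               ax_inverse("II-has-part", "II-part-of")))
  m <- finite_model(c("a", "b", "c", "z"),
                    rel_ext = list("II-part-of" = list(c("a", "b"),
                                                       c("b", "c")),
                                   "II-region-of" = list(c("c", "z"))))
  cm <- closure(m, ax)
  expect_true(okey("a", "c") %in% okeys(cm, "II-part-of"))
  expect_true(okey("a", "z") %in% okeys(cm, "II-region-of"))  # via chain
  expect_true(okey("b", "a") %in% okeys(cm, "II-has-part"))   # via inverse
})

test_that("closure is idempotent and monotone", {
  ax <- small_scope_axioms()
  set.seed(5)
  for (i in 1:40) {
    m <- sample_models(c("C1", "C2"), c("r1", "r2"), 4, 1, seed = 100 + i)[[1L]]
    c1 <- closure(m, ax)
    c2 <- closure(c1, ax)
    expect_true(model_equal(c1, c2))
    # monotone: grow the input, the closure grows
    m2 <- m
    m2$class_ext[["C1"]] <- unique(c(m2$class_ext[["C1"]],
                                     m$individuals[1L]))
    m2$rel_ext[["r1"]] <- unique(rbind(m2$rel_ext[["r1"]],
                                       c(m$individuals[1L],
                                         m$individuals[2L])))
    expect_true(model_subset(c1, closure(m2, ax)))
  }
})

test_that("closure equals the naive full-pass fixpoint oracle on random models", {
  ax <- small_scope_axioms()
  set.seed(11)
  for (i in 1:60) {
    m <- sample_models(c("C1", "C2"), c("r1", "r2"), 5, 1,
                       density = 0.25, seed = 300 + i)[[1L]]
    expect_true(model_equal(closure(m, ax), naive_closure(m, ax)))
  }
})

test_that("check reports flag violations with witnesses", {
  m <- finite_model("g", rel_ext = list("II-has-mutant" = list(c("g", "g"))))
  rep <- check(m, list(), tax)
  expect_true("irreflexivity" %in% rep$category)
  expect_identical(rep$witness[rep$category == "irreflexivity"], "g")
  # asymmetry of membership
  m2 <- finite_model(c("a", "b"),
                     rel_ext = list("II-member-of" = list(c("a", "b"),
                                                          c("b", "a"))))
  rep2 <- check(m2, list(ax_characteristic("II-member-of", "ASYMMETRIC")),
                taxonomy = NULL)
  expect_true("asymmetry" %in% rep2$category)
})

test_that("strong supplementation flags undersupplemented wholes", {
  loops <- function(inds) lapply(inds, function(i) c(i, i))
  # y's only atom is z, and both parts of y (y itself and z) overlap x:
  # strong supplementation then demands y II-oc-part-of x, which is absent
  inds <- c("x", "y", "z", "w")
  rel <- c(loops(inds),
           list(c("z", "x"), c("w", "x"), c("z", "y")))
  m <- finite_model(inds, rel_ext = list("II-oc-part-of" = rel))
  ax <- list(ax_characteristic("II-oc-part-of", "STRONG_SUPPLEMENTATION"))
  rep <- check(m, ax, taxonomy = NULL)
  expect_true("strong-supplementation" %in% rep$category)
  expect_true(any(grepl("x,y", rep$witness, fixed = TRUE)))
  # giving y an atom of its own (v) that does not overlap x satisfies the
  # principle for every pair
  inds2 <- c(inds, "v")
  rel2 <- c(loops(inds2),
            list(c("z", "x"), c("w", "x"), c("z", "y"), c("v", "y")))
  m2 <- finite_model(inds2, rel_ext = list("II-oc-part-of" = rel2))
  rep2 <- check(m2, ax, taxonomy = NULL)
  expect_false("strong-supplementation" %in% rep2$category)
})

test_that("reflexivity checking is domain-restricted by default, global on request", {
  m <- finite_model(c("a", "b", "c"),
                    rel_ext = list("II-part-of" = list(c("a", "a"),
                                                       c("a", "b"),
                                                       c("b", "b"))))
  ax <- list(ax_characteristic("II-part-of", "REFLEXIVE"))
  expect_identical(nrow(check(m, ax, taxonomy = NULL)), 0L)
  repg <- check(m, ax, taxonomy = NULL, reflexivity = "global")
  expect_true("reflexivity" %in% repg$category)
  expect_identical(repg$witness[repg$category == "reflexivity"], "c")
})

test_that("model enumeration is exhaustive with the documented count and guard", {
  expect_length(enumerate_models("C", "r", 1), 4L)
  expect_length(enumerate_models("C", "r", 0), 1L)
  expect_length(enumerate_models(c("C1", "C2"), "r", 1), 2 ^ 3)
  expect_error(enumerate_models("C", c("r1", "r2"), 4, max_models = 1024),
               "guard")
  s1 <- sample_models("C", "r", 4, 5, seed = 9)
  s2 <- sample_models("C", "r", 4, 5, seed = 9)
  for (i in seq_along(s1)) expect_true(model_equal(s1[[i]], s2[[i]]))
})

test_that("check agrees with direct FOL evaluation on exhaustive tiny models", {
  ax <- small_scope_axioms()
  models <- enumerate_models(c("C1", "C2"), c("r1", "r2"), 1)
  for (m in models) {
    cm <- closure(m, ax)
    rep <- check(cm, ax, taxonomy = NULL, close = FALSE)
    expect_setequal(sort(unique(rep$category)), fol_categories(cm, ax))
  }
})

test_that("derivation chains explain inferred pairs", {
  ax <- list(ax_characteristic("II-part-of", "TRANSITIVE"))
  m <- finite_model(c("a", "b", "c"),
                    rel_ext = list("II-part-of" = list(c("a", "b"),
                                                       c("b", "c"))))
  cm <- closure(m, ax)
  txt <- ggprel:::explain_pair(cm, "II-part-of", "a", "c")
  expect_match(txt, "transitivity")
  expect_match(txt, "II-part-of\\(a, b\\)")
})

test_that("the chase builds consistent canonical models for consistent documents", {
  wx <- worked_examples()
  for (nm in c("cd19-equiv", "tnfri-mutant", "oct2-recombinant")) {
    ax <- convert_abstract(wx[[nm]]$annotation, tax)
    m <- canonical_model(ax, tax = tax)
    expect_identical(nrow(check(m, ax, tax)), 0L, info = nm)
  }
})
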