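tax <- genia_taxonomy()

test_that("the GGP class collects the transcription/translation derivation chain", {
  g <- ggp_class("G_CD19",
                 tibble::tibble(class_id = c("CD19_gene", "CD19_protein"),
                                term_class = c("DNA", "Protein")),
                 seed_dna_class = "CD19_gene")
  ax <- define_ggp_class(g, tax)
  m <- finite_model(
    c("d", "r", "p", "q"),
    class_ext = list(CD19_gene = "d"),
    rel_ext = list("transcribed-from" = list(c("r", "d")),
                   "translated-from" = list(c("p", "r"))))
  cm <- closure(m, ax)
  expect_setequal(eval_expr("G_CD19", cm), c("d", "r", "p"))
  # q has no derivation chain and stays outside
  expect_false("q" %in% eval_expr("G_CD19", cm))
})

test_that("GGP class extension equals direct evaluation of the three-disjunct formula", {
  g <- ggp_class("G", tibble::tibble(class_id = "C", term_class = "DNA"),
                 seed_dna_class = "C")
  ax <- define_ggp_class(g, tax)
  set.seed(61)
  for (i in 1:30) {
    m <- sample_models("C", c("transcribed-from", "translated-from"),
                       n = 6, k = 1, density = 0.25, seed = 6000 + i)[[1L]]
    cm <- closure(m, ax)
    # oracle: direct evaluation of C(x) | Ey tf(x,y)&C(y) |
    #         Ey Ez tl(x,y)&tf(y,z)&C(z)
    expected <- character(0)
    for (x in m$individuals) {
      in_c <- x %in% oclass(m, "C")
      d1 <- any(vapply(m$individuals, function(y)
        oholds(m, "transcribed-from", x, y) && y %in% oclass(m, "C"), TRUE))
      d2 <- FALSE
      for (y in m$individuals) for (z in m$individuals) {
        if (oholds(m, "translated-from", x, y) &&
            oholds(m, "transcribed-from", y, z) && z %in% oclass(m, "C")) {
          d2 <- TRUE
        }
      }
      if (in_c || d1 || d2) expected <- c(expected, x)
    }
    expect_setequal(eval_expr("G", cm), expected)
  }
})

test_that("subclass conversion is plain is-a, with a warning on identical classes", {
  ax <- convert_subclass_relation("CD19_human_gene", "CD19_GGP")
  expect_length(ax, 1L)
  expect_identical(ax[[1L]]$type, "subclass")
  ax2 <- convert_subclass_relation("C", "C")
  expect_length(ax2, 2L)
  expect_identical(ax2[[2L]]$type, "annotation")
  expect_match(ax2[[2L]]$text, "identical classes")
})

test_that("the kind-disjunction pattern is satisfied by one kind and violated by none", {
  p <- pattern_instance("G_CD19", "GGP-subclass-has-part", "CD19_promoter")
  ax <- expand_subclass_pattern(p, tax)
  expect_length(ax, 1L)
  expect_identical(ax[[1L]]$pattern$primitive, "II-has-part")
  sat <- finite_model(
    c("d", "p", "pr"),
    class_ext = list(G_CD19 = c("d", "p"), DNA = "d", Protein = "p",
                     CD19_promoter = "pr"),
    rel_ext = list("II-has-part" = list(c("d", "pr"))))
  expect_identical(nrow(check(sat, ax, taxonomy = NULL)), 0L)
  # no kind works: the only DNA member has no part, ditto protein, and all
  # kinds are inhabited
  bad <- finite_model(
    c("d", "p", "r", "pr"),
    class_ext = list(G_CD19 = c("d", "p", "r"), DNA = "d", Protein = "p",
                     RNA = "r", CD19_promoter = "pr"),
    rel_ext = list("II-has-part" = list()))
  rep <- check(bad, ax, taxonomy = NULL)
  expect_true("pattern-subclass-disjunction" %in% rep$category)
  expect_identical(rep$witness[rep$category ==
                                 "pattern-subclass-disjunction"], "universal")
})

test_that("native pattern evaluation agrees with its OWL top-property encoding and a brute-force oracle", {
  p <- pattern_instance("G", "GGP-subclass-member-of", "X",
                        kinds = c("K1", "K2"))
  ax <- expand_subclass_pattern(p, tax)
  encoded <- ax[[1L]]$encoded
  classes <- c("G", "K1", "K2", "X")
  models <- c(enumerate_models(classes, "II-member-of", 2),
              sample_models(classes, "II-member-of", 4, 150, seed = 17))
  for (m in models) {
    native <- nrow(check(m, ax, taxonomy = NULL, close = FALSE)) == 0L
    enc <- length(setdiff(eval_expr(encoded$sub, m),
                          eval_expr(encoded$sup, m))) == 0L
    # brute-force disjunction over kinds
    brute <- any(vapply(c("K1", "K2"), function(k) {
      members <- intersect(oclass(m, "G"), oclass(m, k))
      all(vapply(members, function(x)
        any(vapply(oclass(m, "X"), function(y)
          oholds(m, "II-member-of", x, y), TRUE)), TRUE))
    }, TRUE))
    expect_identical(native, brute)
    expect_identical(enc, brute)
  }
})

test_that("enlarging the primitive extension never breaks a satisfied pattern instance", {
  p <- pattern_instance("G", "GGP-subclass-part-of", "X",
                        kinds = c("K1", "K2"))
  ax <- expand_subclass_pattern(p, tax)
  set.seed(23)
  classes <- c("G", "K1", "K2", "X")
  grown <- 0L
  for (i in 1:60) {
    m <- sample_models(classes, "II-part-of", 4, 1, density = 0.35,
                       seed = 400 + i)[[1L]]
    if (nrow(check(m, ax, taxonomy = NULL, close = FALSE)) > 0L) next
    # add random extra pairs
    extra <- sample_models(character(0), "II-part-of", 4, 1, density = 0.4,
                           seed = 900 + i)[[1L]]
    m2 <- m
    m2$rel_ext[["II-part-of"]] <- unique(rbind(
      m$rel_ext[["II-part-of"]], extra$rel_ext[["II-part-of"]]))
    expect_identical(nrow(check(m2, ax, taxonomy = NULL, close = FALSE)), 0L)
    grown <- grown + 1L
  }
  expect_gt(grown, 5L)
})

test_that("variant patterns use the configured primitive and kind restriction", {
  ax <- expand_variant_pattern(
    pattern_instance("G_TR_alpha_1", "GGP-has-modified-protein",
                     "X35S_TR_alpha_1"), tax)
  expect_length(ax, 1L)
  expect_identical(ax[[1L]]$sup$rel, "II-has-modified-protein")
  expect_identical(ax[[1L]]$sup$filler$args[[2L]]$id, "Protein")
  sat <- finite_model(
    c("t", "mm"),
    class_ext = list(G_TR_alpha_1 = "t", Protein = c("t", "mm"),
                     X35S_TR_alpha_1 = "mm"),
    rel_ext = list("II-has-modified-protein" = list(c("mm", "t"))))
  expect_identical(nrow(check(sat, ax, taxonomy = NULL)), 0L)
  # empty target class: vacuously satisfied in every model
  empty <- finite_model(c("a", "b"), class_ext = list(G_TR_alpha_1 = "a"))
  expect_identical(nrow(check(empty, ax, taxonomy = NULL)), 0L)
  # recombinant restricts the filler to the DNA subclass
  axr <- expand_variant_pattern(
    pattern_instance("G", "GGP-has-recombinant", "V"), tax)
  expect_identical(axr[[1L]]$sup$filler$args[[2L]]$id, "DNA")
  # unrestricted for the generic variant relation
  axv <- expand_variant_pattern(
    pattern_instance("G", "GGP-has-variant", "V"), tax)
  expect_identical(axv[[1L]]$sup$filler$kind, "named")
})

test_that("mutant symmetry closes and a self-loop violates irreflexivity", {
  ax <- c(expand_variant_pattern(
    pattern_instance("G", "GGP-has-mutant", "D"), tax),
    list(ax_characteristic("II-has-mutant", "SYMMETRIC"),
         ax_characteristic("II-has-mutant", "IRREFLEXIVE")))
  m <- finite_model(c("g", "mu"),
                    class_ext = list(G = "g", Protein = "g", D = "mu"),
                    rel_ext = list("II-has-mutant" = list(c("mu", "g"))))
  cm <- closure(m, ax)
  expect_true(okey("g", "mu") %in% okeys(cm, "II-has-mutant"))
  expect_identical(nrow(check(m, ax, taxonomy = NULL)), 0L)
  m2 <- m
  m2$rel_ext[["II-has-mutant"]] <- rbind(m2$rel_ext[["II-has-mutant"]],
                                         c("g", "g"))
  rep <- check(m2, ax, taxonomy = NULL)
  expect_true("irreflexivity" %in% rep$category)
  expect_true("g" %in% rep$witness)
})

test_that("chain relations generalize the variant pattern, ordered or permuted", {
  p <- pattern_instance("G", "GGP-has-variant", "D",
                        chain_relations = c("t1", "t2"))
  ax <- expand_variant_pattern(p, tax)
  sup <- ax[[1L]]$sup
  expect_identical(sup$kind, "or")
  expect_length(sup$args, 2L)
  axp <- expand_variant_pattern(p, tax, permutations = TRUE)
  expect_length(axp[[1L]]$sup$args, 3L)  # direct + 2 orders
})

test_that("proper parthood is parthood minus coincidence", {
  m <- finite_model(c("a", "b"),
                    rel_ext = list("II-part-of" = list(c("a", "a"),
                                                       c("b", "b"),
                                                       c("a", "b"))))
  pp <- proper_part_extension(m)
  expect_identical(nrow(pp), 1L)
  expect_identical(unname(pp[1L, ]), c("a", "b"))
  # mutual parthood excludes both directions
  m2 <- finite_model(c("a", "b"),
                     rel_ext = list("II-part-of" = list(c("a", "b"),
                                                        c("b", "a"))))
  expect_identical(nrow(proper_part_extension(m2)), 0L)
})

test_that("on partial orders, proper part equals part minus identity", {
  set.seed(7)
  for (i in 1:40) {
    inds <- paste0("i", 1:sample(2:4, 1L))
    po <- random_partial_order(inds)
    m <- finite_model(inds, rel_ext = list("II-part-of" = po))
    pp <- proper_part_extension(m)
    nonid <- po[po[, 1L] != po[, 2L], , drop = FALSE]
    expect_setequal(okey(pp[, 1L], pp[, 2L]),
                    okey(nonid[, 1L], nonid[, 2L]))
  }
})

test_that("location propagates along parthood in both compositions", {
  ax <- location_chain_axioms()
  m1 <- finite_model(c("x", "y", "z"),
                     rel_ext = list("II-part-of" = list(c("x", "y")),
                                    "II-region-of" = list(c("y", "z"))))
  expect_true(okey("x", "z") %in% okeys(closure(m1, ax), "II-region-of"))
  m2 <- finite_model(c("x", "y", "z"),
                     rel_ext = list("II-region-of" = list(c("x", "y")),
                                    "II-part-of" = list(c("y", "z"))))
  expect_true(okey("x", "z") %in% okeys(closure(m2, ax), "II-region-of"))
  m3 <- finite_model(c("x", "y", "z"))
  cm3 <- closure(m3, ax)
  expect_identical(nrow(opairs(cm3, "II-region-of")), 0L)
})

test_that("mentions group into GGP classes by equivalence links", {
  wx <- worked_examples()
  g <- build_ggp_classes(wx[["cd19-equiv"]]$annotation)
  expect_length(g, 1L)
  expect_identical(g[[1L]]$id, "G_CD19")
  expect_identical(nrow(g[[1L]]$members), 3L)
  expect_identical(g[[1L]]$seed_dna_class, "CD19_gene")
  # without links: one GGP class per GGP-typed mention
  g2 <- build_ggp_classes(wx[["acta1-isoform"]]$annotation)
  expect_length(g2, 2L)
  expect_setequal(vapply(g2, function(x) x$id, ""),
                  c("G_ACTA1", "G_G_Actin"))
  # two disjoint groups stay two classes
  txt <- "A B C D"
  ann <- paste("T1\tProtein 0 1\tA", "T2\tDNA 2 3\tB",
               "T3\tProtein 4 5\tC", "T4\tDNA 6 7\tD",
               "*\tEquiv T1 T2", "*\tEquiv T3 T4", sep = "\n")
  g3 <- build_ggp_classes(parse_annotation(txt, ann))
  expect_length(g3, 2L)
})

test_that("convert_abstract emits the pattern expansions the mentions call for", {
  wx <- worked_examples()
  ax <- convert_abstract(wx[["cd19-promoter"]]$annotation, tax)
  pats <- Filter(function(a) a$type == "pattern" &&
                   a$pattern$name == "subclass-disjunction", ax)
  expect_length(pats, 1L)
  expect_identical(pats[[1L]]$pattern$relation, "GGP-subclass-has-part")
  expect_identical(pats[[1L]]$pattern$ggp, "G_CD19")
  expect_identical(pats[[1L]]$pattern$target, "CD19_promoter")
  axh <- convert_abstract(wx[["hoxa1-family"]]$annotation, tax)
  path <- Filter(function(a) a$type == "pattern" &&
                   a$pattern$name == "subclass-disjunction", axh)
  expect_identical(path[[1L]]$pattern$relation, "GGP-subclass-member-of")
  # zero relations: declarations and background only, no pattern instances
  ax0 <- convert_abstract(wx[["cd19-equiv"]]$annotation, tax)
  expect_length(Filter(function(a) a$type == "pattern" &&
                         a$pattern$name == "subclass-disjunction", ax0), 0L)
  # determinism
  ax0b <- convert_abstract(wx[["cd19-equiv"]]$annotation, tax)
  expect_identical(vapply(ax0, axiom_str, ""), vapply(ax0b, axiom_str, ""))
})

test_that("unmapped labels raise an error naming label and position", {
  wx <- worked_examples()
  a <- wx[["cd19-promoter"]]$annotation
  a$relations$label <- "No-Such-Label"
  expect_error(convert_abstract(a, tax),
               "R1.*unmapped relation label 'No-Such-Label'")
})

test_that("class identifiers are minted deterministically from surfaces", {
  expect_identical(mint_class_id("CD19/CD21/CD81/Leu-13 complex"),
                   "CD19_CD21_CD81_Leu_13_complex")
  expect_identical(mint_class_id("  TR alpha 1 "), "TR_alpha_1")
  expect_error(mint_class_id("  !! "))
})
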