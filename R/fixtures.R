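#' @title Fixture generation
#' @description Builds, without any download, annotation documents and finite
#'   models reproducing the worked examples of the relation formalization,
#'   plus seeded randomized valid/corrupted corpora for property tests.
#'   Abstract texts are short synthetic sentences embedding the entity names;
#'   no corpus text is redistributed.
#' @name ggprel-fixtures
NULL

# Build an annotation from (class, surface, occurrence) term descriptors;
# offsets are located in the text automatically.
fixture_doc <- function(doc_id, text, terms, rels = list(), equivs = list()) {
  rows <- list()
  for (i in seq_along(terms)) {
    tm <- terms[[i]]
    occ <- if (is.null(tm$occ)) 1L else tm$occ
    hits <- gregexpr(tm$surface, text, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L || length(hits) < occ) {
      stop("fixture ", doc_id, ": occurrence ", occ, " of ",
           dQuote(tm$surface), " not found")
    }
    start <- hits[occ] - 1L
    rows[[i]] <- tibble::tibble(
      id = paste0("T", i), term_class = tm$class,
      start = start, end = start + nchar(tm$surface), surface = tm$surface)
  }
  rel_rows <- NULL
  if (length(rels)) {
    rel_rows <- do.call(rbind, lapply(seq_along(rels), function(i) {
      tibble::tibble(id = paste0("R", i), label = rels[[i]]$label,
                     arg1 = rels[[i]]$arg1, arg2 = rels[[i]]$arg2)
    }))
  }
  abstract_annotation(doc_id, text, terms = do.call(rbind, rows),
                      relations = rel_rows, equivs = equivs)
}

VARIANT_RELS <- c("II-has-variant", "II-has-isoform", "II-has-mutant",
                  "II-has-recombinant", "II-has-precursor",
                  "II-has-modified-protein", "II-has-experimental-material")

# Add reflexive self-loops required by the reflexivity axioms: parthood for
# every individual, variance when a variance relation is in play.
pad_reflexive <- function(m) {
  loops <- cbind(m$individuals, m$individuals)
  add_loops <- function(m, rel) {
    m$rel_ext[[rel]] <- as_pairs(rbind(model_pairs(m, rel), loops))
    m
  }
  m <- add_loops(m, "II-part-of")
  if (any(VARIANT_RELS %in% names(m$rel_ext))) {
    m <- add_loops(m, "II-has-variant")
  }
  if ("II-oc-part-of" %in% names(m$rel_ext)) {
    m <- add_loops(m, "II-oc-part-of")
  }
  m
}

fm <- function(inds, cls = list(), rels = list()) {
  pad_reflexive(finite_model(inds, class_ext = cls, rel_ext = rels))
}

#' Worked-example fixtures
#'
#' The in-text worked examples as ready-made fixtures: the CD19 equivalence
#' trio, CD19 promoter component, CD19 locus location, human CD19 gene
#' subclass, HOXA1/Hox gene family and Lck/Src family membership, the six
#' variance examples (35S-TR alpha 1, G-Actin, dominant-negative mutant
#' TNFRI, Oct-2 expression vector, pro-IL-16, antisense GATA-3 RNA), a plain
#' variant document, a consistent component-of-complex document, and the
#' faulty-schema document in which the generic class-level parthood schema
#' over-generalizes (deriving that a promoter is part of a protein complex)
#' while the GGP-subclass pattern does not.
#'
#' @return Named list of entries, each with `annotation` (an
#'   [abstract_annotation()]), `model` (a [finite_model()] realizing the
#'   document's facts), `tag` (`"consistent"` or
#'   `"inconsistent-under-generic-schema"`), and -- for the faulty-schema
#'   document -- `pattern_model`, the same class-level facts realized the
#'   way the pattern reads them (part-bearing DNA subclass distinct from the
#'   complex-bound protein subclass).
#' @export
worked_examples <- function() {
  out <- list()

  out$`cd19-equiv` <- list(
    annotation = fixture_doc(
      "cd19-equiv",
      "CD19 is encoded by the CD19 gene and expressed as the CD19 protein in B cells .",
      list(list(class = "Protein", surface = "CD19"),
           list(class = "DNA", surface = "CD19 gene"),
           list(class = "Protein", surface = "CD19 protein")),
      equivs = list(c("T1", "T2", "T3"))),
    model = fm(c("d", "r", "p"),
               cls = list(CD19_gene = "d", RNA = "r", CD19 = "p"),
               rels = list("transcribed-from" = list(c("r", "d")),
                           "translated-from" = list(c("p", "r")))),
    tag = "consistent")

  out$`cd19-promoter` <- list(
    annotation = fixture_doc(
      "cd19-promoter",
      "The CD19 promoter drives B cell specific expression of CD19 .",
      list(list(class = "DNA_domain_or_region", surface = "CD19 promoter"),
           list(class = "Protein", surface = "CD19", occ = 2L)),
      rels = list(list(label = "Object-Component", arg1 = "T2",
                       arg2 = "T1"))),
    model = fm(c("d", "pr", "p"),
               cls = list(G_CD19 = c("d", "p"), DNA = "d",
                          CD19_promoter = "pr", CD19 = "p"),
               rels = list("II-has-part" = list(c("d", "pr")))),
    tag = "consistent")

  out$`cd19-locus` <- list(
    annotation = fixture_doc(
      "cd19-locus",
      "CD19 is located at the CD19 locus .",
      list(list(class = "Protein", surface = "CD19"),
           list(class = "DNA_domain_or_region", surface = "CD19 locus")),
      rels = list(list(label = "Object-Region", arg1 = "T1", arg2 = "T2"))),
    model = fm(c("d", "l"),
               cls = list(G_CD19 = "d", DNA = "d", CD19_locus = "l"),
               rels = list("II-region-of" = list(c("d", "l")))),
    tag = "consistent")

  out$`cd19-human` <- list(
    annotation = fixture_doc(
      "cd19-human",
      "The human CD19 gene is related to CD19 .",
      list(list(class = "DNA", surface = "human CD19 gene"),
           list(class = "Protein", surface = "CD19", occ = 2L)),
      rels = list(list(label = "Subclass", arg1 = "T1", arg2 = "T2"))),
    model = fm("h", cls = list(human_CD19_gene = "h", DNA = "h")),
    tag = "consistent")

  out$`hoxa1-family` <- list(
    annotation = fixture_doc(
      "hoxa1-family",
      "HOXA1 is a member of the Hox gene family .",
      list(list(class = "DNA", surface = "HOXA1"),
           list(class = "DNA_family_or_group", surface = "Hox gene family")),
      rels = list(list(label = "Member-Collection", arg1 = "T1",
                       arg2 = "T2"))),
    model = fm(c("h", "f"),
               cls = list(HOXA1 = "h", DNA = "h", Hox_gene_family = "f"),
               rels = list("II-member-of" = list(c("h", "f")))),
    tag = "consistent")

  out$`lck-src` <- list(
    annotation = fixture_doc(
      "lck-src",
      "Lck is a member of the Src family of protein tyrosine kinases .",
      list(list(class = "Protein", surface = "Lck"),
           list(class = "Protein_family_or_group", surface = "Src family")),
      rels = list(list(label = "Member-Collection", arg1 = "T1",
                       arg2 = "T2"))),
    model = fm(c("l", "f"),
               cls = list(Lck = "l", Src_family = "f"),
               rels = list("II-member-of" = list(c("l", "f")))),
    tag = "consistent")

  out$`tr-alpha-1` <- list(
    annotation = fixture_doc(
      "tr-alpha-1",
      "The 35S-TR alpha 1 protein is a modified form of TR alpha 1 .",
      list(list(class = "Protein", surface = "TR alpha 1", occ = 2L),
           list(class = "Protein", surface = "35S-TR alpha 1")),
      rels = list(list(label = "Object-Variant-Modified-Protein",
                       arg1 = "T1", arg2 = "T2"))),
    model = fm(c("t", "mm"),
               cls = list(TR_alpha_1 = "t", `35S_TR_alpha_1` = "mm"),
               rels = list("II-has-modified-protein" = list(c("mm", "t")))),
    tag = "consistent")

  out$`acta1-isoform` <- list(
    annotation = fixture_doc(
      "acta1-isoform",
      "G-Actin is an isoform of the protein encoded by ACTA1 .",
      list(list(class = "Protein", surface = "ACTA1"),
           list(class = "Protein", surface = "G-Actin")),
      rels = list(list(label = "Object-Variant-Isoform", arg1 = "T1",
                       arg2 = "T2"))),
    model = fm(c("a", "gi"),
               cls = list(ACTA1 = "a", G_Actin = "gi"),
               rels = list("II-has-isoform" = list(c("gi", "a")))),
    tag = "consistent")

  out$`tnfri-mutant` <- list(
    annotation = fixture_doc(
      "tnfri-mutant",
      "A dominant-negative mutant TNFRI inhibits signalling by TNFRI .",
      list(list(class = "Protein", surface = "TNFRI", occ = 2L),
           list(class = "Protein",
                surface = "dominant-negative mutant TNFRI")),
      rels = list(list(label = "Object-Variant-Mutant", arg1 = "T1",
                       arg2 = "T2"))),
    model = fm(c("t", "mu"),
               cls = list(TNFRI = "t", dominant_negative_mutant_TNFRI = "mu"),
               rels = list("II-has-mutant" = list(c("mu", "t")))),
    tag = "consistent")

  out$`oct2-recombinant` <- list(
    annotation = fixture_doc(
      "oct2-recombinant",
      "An Oct-2 expression vector was used to overexpress Oct-2 .",
      list(list(class = "Protein", surface = "Oct-2", occ = 2L),
           list(class = "DNA", surface = "Oct-2 expression vector")),
      rels = list(list(label = "Object-Variant-Recombinant", arg1 = "T1",
                       arg2 = "T2"))),
    model = fm(c("od", "v"),
               cls = list(G_Oct_2 = "od", DNA = "od",
                          Oct_2_expression_vector = "v"),
               rels = list("II-has-recombinant" = list(c("v", "od")))),
    tag = "consistent")

  out$`il16-precursor` <- list(
    annotation = fixture_doc(
      "il16-precursor",
      "Pro-IL-16 is cleaved to yield mature IL-16 .",
      list(list(class = "Protein", surface = "IL-16", occ = 2L),
           list(class = "Protein", surface = "Pro-IL-16")),
      rels = list(list(label = "Object-Variant-Precursor", arg1 = "T1",
                       arg2 = "T2"))),
    model = fm(c("i", "pp"),
               cls = list(IL_16 = "i", Pro_IL_16 = "pp"),
               rels = list("II-has-precursor" = list(c("pp", "i")))),
    tag = "consistent")

  out$`gata3-antisense` <- list(
    annotation = fixture_doc(
      "gata3-antisense",
      "Antisense GATA-3 RNA was expressed to block GATA-3 .",
      list(list(class = "Protein", surface = "GATA-3", occ = 2L),
           list(class = "RNA", surface = "Antisense GATA-3 RNA")),
      rels = list(list(label = "Object-Variant-Experimental-Material",
                       arg1 = "T1", arg2 = "T2"))),
    model = fm(c("g", "ar"),
               cls = list(GATA_3 = "g", Antisense_GATA_3_RNA = "ar"),
               rels = list("II-has-experimental-material" =
                             list(c("ar", "g")))),
    tag = "consistent")

  out$`gata3-variant` <- list(
    annotation = fixture_doc(
      "gata3-variant",
      "A GATA-3V variant of GATA-3 was detected .",
      list(list(class = "Protein", surface = "GATA-3", occ = 2L),
           list(class = "Protein", surface = "GATA-3V")),
      rels = list(list(label = "Object-Variant", arg1 = "T1",
                       arg2 = "T2"))),
    model = fm(c("g", "v"),
               cls = list(GATA_3 = "g", GATA_3V = "v"),
               rels = list("II-has-variant" = list(c("v", "g")))),
    tag = "consistent")

  out$`cd19-complex` <- list(
    annotation = fixture_doc(
      "cd19-complex",
      "CD19 is a component of the CD19/CD21/CD81/Leu-13 complex .",
      list(list(class = "Protein", surface = "CD19"),
           list(class = "Protein_complex",
                surface = "CD19/CD21/CD81/Leu-13 complex")),
      rels = list(list(label = "Component-Object", arg1 = "T1",
                       arg2 = "T2"))),
    model = fm(c("p", "cx"),
               cls = list(CD19 = "p",
                          CD19_CD21_CD81_Leu_13_complex = "cx"),
               rels = list("II-part-of" = list(c("p", "cx")))),
    tag = "consistent")

  # The headline counterexample: a promoter is part of CD19 and CD19 is part
  # of a protein complex. Read with the generic class-level schema on a
  # single CD19 individual, transitivity derives that the promoter is part
  # of the complex, clashing with the constraint that protein complexes
  # have no promoter parts. Read with the GGP-subclass pattern, the
  # part-bearing subclass is the DNA subclass and the complex-bound one the
  # protein subclass, so no faulty chain exists.
  out$`cd19-faulty` <- list(
    annotation = fixture_doc(
      "cd19-faulty",
      "The CD19 promoter is part of CD19 , and CD19 is part of the CD19/CD21/CD81/Leu-13 complex .",
      list(list(class = "DNA_domain_or_region", surface = "CD19 promoter"),
           list(class = "Protein", surface = "CD19", occ = 2L),
           list(class = "Protein_complex",
                surface = "CD19/CD21/CD81/Leu-13 complex")),
      rels = list(list(label = "Object-Component", arg1 = "T2", arg2 = "T1"),
                  list(label = "Component-Object", arg1 = "T2",
                       arg2 = "T3"))),
    model = fm(c("pr", "g", "cx"),
               cls = list(CD19_promoter = "pr", CD19 = "g",
                          CD19_CD21_CD81_Leu_13_complex = "cx"),
               rels = list("II-has-part" = list(c("g", "pr")),
                           "II-part-of" = list(c("g", "cx")))),
    pattern_model = fm(c("pr", "d", "p", "cx"),
                       cls = list(CD19_promoter = "pr", CD19 = "p",
                                  DNA = "d", G_CD19 = "d",
                                  CD19_CD21_CD81_Leu_13_complex = "cx"),
                       rels = list("II-has-part" = list(c("d", "pr")),
                                   "II-part-of" = list(c("p", "cx")))),
    tag = "inconsistent-under-generic-schema")

  out
}

# ---- randomized corpora -----------------------------------------------------

RND_GENES <- c("ABC1", "TP53", "GATA3", "IL2", "STAT6", "NFKB1", "CD28",
               "FOXP3", "IRF4", "TBX21")
RND_FAMILIES <- c("Src family", "Rel family", "STAT family", "Ets family")
RND_COMPLEXES <- c("NF-kappa-B/I-kappa-B complex", "TCR/CD3 complex",
                   "AP-1 complex")

CORRUPTION_TYPES <- c("mutant-self-loop", "membership-cycle",
                      "kind-disjointness-clash", "dangling-arg")

# Template builders: each returns list(annotation, model).
rnd_templates <- function() {
  list(
    component = function(id, g, ...) {
      a <- fixture_doc(id,
        paste0("The ", g, " promoter regulates ", g, " ."),
        list(list(class = "DNA_domain_or_region",
                  surface = paste0(g, " promoter")),
             list(class = "Protein", surface = g, occ = 2L)),
        rels = list(list(label = "Object-Component", arg1 = "T2",
                         arg2 = "T1")))
      gid <- paste0("G_", mint_class_id(g))
      m <- fm(c("d", "pr"),
              cls = stats::setNames(list("d", "d", "pr"),
                c(gid, "DNA", mint_class_id(paste0(g, " promoter")))),
              rels = list("II-has-part" = list(c("d", "pr"))))
      list(annotation = a, model = m)
    },
    part = function(id, g, cx, ...) {
      a <- fixture_doc(id,
        paste0(g, " is a component of the ", cx, " ."),
        list(list(class = "Protein", surface = g),
             list(class = "Protein_complex", surface = cx)),
        rels = list(list(label = "Component-Object", arg1 = "T1",
                         arg2 = "T2")))
      m <- fm(c("p", "c"),
              cls = stats::setNames(list("p", "c"),
                c(mint_class_id(g), mint_class_id(cx))),
              rels = list("II-part-of" = list(c("p", "c"))))
      list(annotation = a, model = m)
    },
    member = function(id, g, fam, ...) {
      a <- fixture_doc(id,
        paste0(g, " is a member of the ", fam, " ."),
        list(list(class = "Protein", surface = g),
             list(class = "Protein_family_or_group", surface = fam)),
        rels = list(list(label = "Member-Collection", arg1 = "T1",
                         arg2 = "T2")))
      m <- fm(c("p", "f"),
              cls = stats::setNames(list("p", "f"),
                c(mint_class_id(g), mint_class_id(fam))),
              rels = list("II-member-of" = list(c("p", "f"))))
      list(annotation = a, model = m)
    },
    region = function(id, g, ...) {
      a <- fixture_doc(id,
        paste0(g, " is located at the ", g, " locus ."),
        list(list(class = "Protein", surface = g),
             list(class = "DNA_domain_or_region",
                  surface = paste0(g, " locus"))),
        rels = list(list(label = "Object-Region", arg1 = "T1",
                         arg2 = "T2")))
      gid <- paste0("G_", mint_class_id(g))
      m <- fm(c("d", "l"),
              cls = stats::setNames(list("d", "d", "l"),
                c(gid, "DNA", mint_class_id(paste0(g, " locus")))),
              rels = list("II-region-of" = list(c("d", "l"))))
      list(annotation = a, model = m)
    },
    subclass = function(id, g, ...) {
      a <- fixture_doc(id,
        paste0("The human ", g, " gene is related to ", g, " ."),
        list(list(class = "DNA", surface = paste0("human ", g, " gene")),
             list(class = "Protein", surface = g, occ = 2L)),
        rels = list(list(label = "Subclass", arg1 = "T1", arg2 = "T2")))
      m <- fm("h",
              cls = stats::setNames(list("h", "h"),
                c(mint_class_id(paste0("human ", g, " gene")), "DNA")))
      list(annotation = a, model = m)
    },
    equiv = function(id, g, ...) {
      a <- fixture_doc(id,
        paste0(g, " is encoded by the ", g, " gene ."),
        list(list(class = "Protein", surface = g),
             list(class = "DNA", surface = paste0(g, " gene"))),
        equivs = list(c("T1", "T2")))
      m <- fm(c("d", "r", "p"),
              cls = stats::setNames(list("d", "r", "p"),
                c(mint_class_id(paste0(g, " gene")), "RNA",
                  mint_class_id(g))),
              rels = list("transcribed-from" = list(c("r", "d")),
                          "translated-from" = list(c("p", "r"))))
      list(annotation = a, model = m)
    },
    variant = function(id, g, ...) {
      variant_template(id, g, paste0(g, "-var"), "Protein",
                       "Object-Variant", "II-has-variant",
                       paste0("A ", g, "-var variant of ", g,
                              " was detected ."))
    },
    modified = function(id, g, ...) {
      variant_template(id, g, paste0("35S-", g), "Protein",
                       "Object-Variant-Modified-Protein",
                       "II-has-modified-protein",
                       paste0("The 35S-", g,
                              " protein is a modified form of ", g, " ."))
    },
    isoform = function(id, g, ...) {
      variant_template(id, g, paste0(g, "-beta"), "Protein",
                       "Object-Variant-Isoform", "II-has-isoform",
                       paste0(g, "-beta is an isoform of ", g, " ."))
    },
    mutant = function(id, g, ...) {
      variant_template(id, g, paste0("dominant-negative mutant ", g),
                       "Protein", "Object-Variant-Mutant", "II-has-mutant",
                       paste0("A dominant-negative mutant ", g,
                              " inhibits ", g, " ."))
    },
    recombinant = function(id, g, ...) {
      variant_template(id, g, paste0(g, " expression vector"), "DNA",
                       "Object-Variant-Recombinant", "II-has-recombinant",
                       paste0("An ", g,
                              " expression vector was used to overexpress ",
                              g, " ."), dna_filler = TRUE)
    },
    precursor = function(id, g, ...) {
      variant_template(id, g, paste0("Pro-", g), "Protein",
                       "Object-Variant-Precursor", "II-has-precursor",
                       paste0("Pro-", g, " is cleaved to yield mature ", g,
                              " ."))
    },
    experimental = function(id, g, ...) {
      variant_template(id, g, paste0("Antisense ", g, " RNA"), "RNA",
                       "Object-Variant-Experimental-Material",
                       "II-has-experimental-material",
                       paste0("Antisense ", g, " RNA was used to block ", g,
                              " ."))
    }
  )
}

variant_template <- function(id, g, vsurf, vclass, label, prim, text,
                             dna_filler = FALSE) {
  a <- fixture_doc(id, text,
    list(list(class = "Protein", surface = g, occ = 2L),
         list(class = vclass, surface = vsurf)),
    rels = list(list(label = label, arg1 = "T1", arg2 = "T2")))
  gcls <- mint_class_id(g)
  vcls <- mint_class_id(vsurf)
  cls <- if (dna_filler) {
    # the filler must sit in the DNA subclass of the GGP class
    stats::setNames(list("t", "t", "v"),
                    c(paste0("G_", gcls), "DNA", vcls))
  } else {
    stats::setNames(list("t", "v"), c(gcls, vcls))
  }
  m <- fm(c("t", "v"), cls = cls,
          rels = stats::setNames(list(list(c("v", "t"))), prim))
  list(annotation = a, model = m)
}

#' Generate a randomized annotation corpus
#'
#' Draws `n_docs` documents from template grammars over the full relation
#' vocabulary (component, parthood, membership, location, subclass,
#' equivalence, and the six variance relations), each paired with a finite
#' model realizing its facts. With probability `corruption_rate` a document
#' receives one labeled corruption from a typed menu: a mutant self-loop
#' (irreflexivity breach), a membership cycle (asymmetry breach), a
#' kind-disjointness clash (one individual typed as both DNA and protein),
#' or a dangling relation argument (standoff well-formedness breach,
#' detected at parse time). Output is deterministic for a fixed seed.
#'
#' @param n_docs number of documents.
#' @param seed integer seed.
#' @param corruption_rate probability in `[0, 1]` that a document is
#'   corrupted.
#' @return List of entries: `doc_id`, `txt`, `ann` (serialized standoff),
#'   `annotation` and `model` (`NULL` for dangling-arg corruptions, whose
#'   standoff does not parse), `corruption` (`NA` or the menu type), and
#'   `expected_category` (`NA`, a violation category, or `"parse-error"`).
#' @export
random_corpus <- function(n_docs, seed, corruption_rate = 0) {
  if (!is.numeric(corruption_rate) || corruption_rate < 0 ||
      corruption_rate > 1) {
    stop("corruption_rate must be in [0, 1]")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  templates <- rnd_templates()
  out <- vector("list", n_docs)
  for (i in seq_len(n_docs)) {
    doc_id <- sprintf("rnd%03d", i)
    corrupt <- stats::runif(1) < corruption_rate
    ctype <- if (corrupt) sample(CORRUPTION_TYPES, 1L) else NA_character_
    g <- sample(RND_GENES, 1L)
    fam <- sample(RND_FAMILIES, 1L)
    cx <- sample(RND_COMPLEXES, 1L)
    tpl_name <- switch(ifelse(is.na(ctype), "none", ctype),
      `mutant-self-loop` = "mutant",
      `membership-cycle` = "member",
      `kind-disjointness-clash` = "part",
      `dangling-arg` = "component",
      sample(names(templates), 1L))
    built <- templates[[tpl_name]](doc_id, g, if (tpl_name == "member") fam
                                   else cx)
    entry <- list(doc_id = doc_id, corruption = ctype,
                  expected_category = NA_character_)
    if (identical(ctype, "dangling-arg")) {
      ser <- write_annotation(built$annotation)
      entry$txt <- ser$txt
      entry$ann <- paste0(ser$ann, "\nR9\t", "Object-Component",
                          " Arg1:T1 Arg2:T99")
      entry$annotation <- NULL
      entry$model <- NULL
      entry$expected_category <- "parse-error"
    } else {
      a <- built$annotation
      m <- built$model
      if (identical(ctype, "mutant-self-loop")) {
        # A second mutant relation whose argument resolves to the GGP's own
        # class: the document then requires each instance to be its own
        # mutant, visible both in the annotation and in the model.
        a <- fixture_doc(doc_id,
          paste0("A dominant-negative mutant ", g, " inhibits ", g, " ."),
          list(list(class = "Protein", surface = g, occ = 2L),
               list(class = "Protein",
                    surface = paste0("dominant-negative mutant ", g)),
               list(class = "Protein", surface = g, occ = 1L)),
          rels = list(list(label = "Object-Variant-Mutant", arg1 = "T1",
                           arg2 = "T2"),
                      list(label = "Object-Variant-Mutant", arg1 = "T1",
                           arg2 = "T3")))
        m$rel_ext[["II-has-mutant"]] <- as_pairs(rbind(
          model_pairs(m, "II-has-mutant"), c("t", "t")))
        entry$expected_category <- "irreflexivity"
      } else if (identical(ctype, "membership-cycle")) {
        m$rel_ext[["II-member-of"]] <- as_pairs(rbind(
          model_pairs(m, "II-member-of"), c("f", "p")))
        entry$expected_category <- "asymmetry"
      } else if (identical(ctype, "kind-disjointness-clash")) {
        m$class_ext[["DNA"]] <- unique(c(model_class(m, "DNA"), "p"))
        m$class_ext[["Protein"]] <- unique(c(model_class(m, "Protein"), "p"))
        entry$expected_category <- "disjointness"
      }
      ser <- write_annotation(a)
      entry$txt <- ser$txt
      entry$ann <- ser$ann
      entry$annotation <- a
      entry$model <- m
    }
    out[[i]] <- entry
  }
  out
}
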