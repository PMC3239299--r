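#' Gene/gene-product class description
#'
#' A GGP class groups term-mention classes considered indistinguishable in
#' the annotation (e.g. \code{CD19}, \code{CD19 protein}, \code{CD19 gene}).
#' If the group contains a DNA-typed member, that member is the seed class
#' `C` from which the GGP class `G_C` is defined through chains of
#' transcription and translation between individuals.
#'
#' @param id identifier of the GGP class (conventionally `G_<name>`).
#' @param members data frame with columns `class_id` and `term_class`, one
#'   row per member class.
#' @param seed_dna_class identifier of the DNA-typed seed class, or `NULL`
#'   when the group has no DNA member (the GGP class is then declared
#'   primitively).
#' @return An object of class `ggprel_ggp`.
#' @export
ggp_class <- function(id, members, seed_dna_class = NULL) {
  members <- tibble::as_tibble(members)
  stopifnot(all(c("class_id", "term_class") %in% names(members)))
  if (!is.null(seed_dna_class) &&
      !seed_dna_class %in% members$class_id) {
    stop("seed class ", seed_dna_class, " is not a member of GGP class ", id)
  }
  structure(list(id = id, members = members,
                 seed_dna_class = seed_dna_class),
            class = "ggprel_ggp")
}

#' @export
print.ggprel_ggp <- function(x, ...) {
  cat("<GGP class> ", x$id, " (", nrow(x$members), " member classes",
      if (!is.null(x$seed_dna_class)) paste0(", seed ", x$seed_dna_class),
      ")\n", sep = "")
  invisible(x)
}

#' Define a GGP class from its DNA seed
#'
#' Produces the defining axioms of a GGP class: `G_C` is equivalent to the
#' union of the seed class `C`, everything transcribed from an instance of
#' `C`, and everything translated from something transcribed from an instance
#' of `C`. On a finite model this makes the extension of `G_C` exactly the
#' individuals reachable from `C` through the transcription/translation
#' derivation chain.
#'
#' @param g a [ggp_class()] with a non-`NULL` seed.
#' @param tax the relation taxonomy (must declare `transcribed-from` and
#'   `translated-from`).
#' @return List of axioms: `SubClassOf(G_C, GGP)` and the defining class
#'   equivalence.
#' @export
define_ggp_class <- function(g, tax = genia_taxonomy()) {
  stopifnot(inherits(g, "ggprel_ggp"))
  if (is.null(g$seed_dna_class)) {
    stop("GGP class ", g$id, " has no DNA seed; declare it primitively")
  }
  for (r in c("transcribed-from", "translated-from")) {
    if (is.null(tax$specs[[r]])) {
      stop("configuration error: taxonomy lacks relation '", r, "'")
    }
  }
  seed <- ce_named(g$seed_dna_class)
  list(
    ax_subclass(g$id, "GGP"),
    ax_equivalent(
      ce_named(g$id),
      ce_or(seed,
            ce_some("transcribed-from", seed),
            ce_some("translated-from", ce_some("transcribed-from", seed))))
  )
}

#' Convert a class-subclass annotation
#'
#' The class-subclass relation is the ontological is-a: every instance of the
#' sub class is an instance of the super class. Identical arguments are
#' emitted but flagged with a warning annotation, since co-extensional
#' classes are not annotated as standing in is-a.
#'
#' @param sub,sup class identifiers.
#' @param provenance optional provenance string.
#' @return List of axioms.
#' @export
convert_subclass_relation <- function(sub, sup, provenance = NULL) {
  out <- list(ax_subclass(sub, sup, provenance = provenance))
  if (identical(sub, sup)) {
    out <- c(out, list(ax_annotation(
      sub, paste0("warning: reflexive is-a annotation on ", sub,
                  "; identical classes are not annotated"),
      provenance = provenance)))
  }
  out
}

#' Pattern instance
#'
#' Parameters of one ontology-design-pattern application: the GGP class, the
#' GGP-level relation, the target class, the kind subclasses the disjunction
#' ranges over (first pattern), and optional chain relations (second
#' pattern's generalization).
#'
#' @param ggp_class GGP class identifier.
#' @param relation GGP-level relation identifier.
#' @param target target class identifier.
#' @param kinds ordered kind classes (default `DNA`, `RNA`, `Protein`).
#' @param chain_relations optional relation identifiers `T_1 ... T_m`.
#' @return An object of class `ggprel_pattern_instance`.
#' @export
pattern_instance <- function(ggp_class, relation, target,
                             kinds = c("DNA", "RNA", "Protein"),
                             chain_relations = NULL) {
  structure(list(ggp_class = ggp_class, relation = relation, target = target,
                 kinds = kinds, chain_relations = chain_relations),
            class = "ggprel_pattern_instance")
}

#' Expand the subclass (kind-disjunction) pattern
#'
#' First ontology design pattern: `GGP-subclass-R(G_C, X)` holds when for at
#' least one kind `K` among the kind subclasses, every instance of
#' `G_C and K` stands in the primitive relation `II-R` to some instance of
#' `X`. A disjunction of axioms is not OWL syntax, so the emitted OWL
#' encoding uses the universal (top) property to turn each disjunct's
#' negation into a nonemptiness claim:
#' the intersection over kinds `K` of
#' `some(top, G_C and K and not some(II-R, X))` is a subclass of
#' `owl:Nothing`. The returned axiom additionally carries the
#' machine-readable pattern parameters so the model checker can evaluate the
#' disjunction natively.
#'
#' @param p a [pattern_instance()] whose relation is one of the
#'   `GGP-subclass-*` relations.
#' @param tax the relation taxonomy.
#' @param provenance optional provenance string.
#' @return List with one pattern axiom (carrying the OWL encoding).
#' @export
expand_subclass_pattern <- function(p, tax = genia_taxonomy(),
                                    provenance = NULL) {
  stopifnot(inherits(p, "ggprel_pattern_instance"), length(p$kinds) >= 1L)
  sp <- tax$specs[[p$relation]]
  if (is.null(sp) || sp$level != "GGP" || is.null(sp$defined_from)) {
    stop("configuration error: '", p$relation,
         "' is not a GGP-level relation with a defined_from primitive")
  }
  prim <- sp$defined_from
  g <- ce_named(p$ggp_class)
  x <- ce_named(p$target)
  counterexample <- function(k) {
    ce_some("owl:topObjectProperty",
            ce_and(g, ce_named(k), ce_not(ce_some(prim, x))))
  }
  lhs <- if (length(p$kinds) == 1L) {
    counterexample(p$kinds[[1L]])
  } else {
    do.call(ce_and, lapply(p$kinds, counterexample))
  }
  encoded <- ax_subclass(lhs, ce_nothing(), provenance = provenance)
  list(ax_pattern("subclass-disjunction",
                  ggp = p$ggp_class, relation = p$relation, primitive = prim,
                  target = p$target, kinds = p$kinds,
                  encoded = encoded, provenance = provenance))
}

#' Expand the variant pattern
#'
#' Second ontology design pattern: `GGP-has-variant(G_C, D)` holds when every
#' instance of `D` is a variant of some instance of `G_C` --
#' `SubClassOf(D, some(II-has-variant, G_C))`. Kind-restricted sub-relations
#' (isoform, mutant, precursor, modified-protein restrict the filler to the
#' Protein subclass; recombinant to the DNA subclass) use
#' `G_C and <kind>` as filler and their own variance primitive. When
#' `chain_relations` are given, the generalized pattern also accepts targets
#' reachable through the chain `T_1 ... T_m` from an instance of the target
#' class, either in the given order or (with `permutations = TRUE`) in any
#' order.
#'
#' @param p a [pattern_instance()] whose relation is `GGP-has-variant` or one
#'   of its sub-relations.
#' @param tax the relation taxonomy.
#' @param kind_restrictions named character vector overriding the taxonomy's
#'   kind-restriction table (names are GGP relation ids).
#' @param permutations consider arbitrary permutations of the chain relations
#'   instead of the given order.
#' @param provenance optional provenance string.
#' @return List with one `SubClassOf` axiom.
#' @export
expand_variant_pattern <- function(p, tax = genia_taxonomy(),
                                   kind_restrictions = character(0),
                                   permutations = FALSE,
                                   provenance = NULL) {
  stopifnot(inherits(p, "ggprel_pattern_instance"))
  sp <- tax$specs[[p$relation]]
  ok <- !is.null(sp) && sp$level == "GGP" &&
    (p$relation == "GGP-has-variant" ||
       "GGP-has-variant" %in% tax_ancestors(tax, p$relation))
  if (!ok) {
    stop("configuration error: '", p$relation,
         "' is not GGP-has-variant or one of its sub-relations")
  }
  prim <- sp$defined_from
  if (is.null(prim) || is.null(tax$specs[[prim]])) {
    stop("configuration error: '", p$relation,
         "' lacks a configured variance primitive")
  }
  kind <- if (p$relation %in% names(kind_restrictions)) {
    kr <- kind_restrictions[[p$relation]]
    if (identical(kr, "") || identical(kr, "unrestricted")) NULL else kr
  } else {
    sp$kind_restriction
  }
  filler <- if (is.null(kind)) {
    ce_named(p$ggp_class)
  } else {
    ce_and(ce_named(p$ggp_class), ce_named(kind))
  }
  sup <- ce_some(prim, filler)
  if (!is.null(p$chain_relations) && length(p$chain_relations) > 0L) {
    chain_expr <- function(rels) {
      e <- filler
      for (r in rev(rels)) e <- ce_some(r, e)
      ce_some(prim, e)
    }
    alts <- if (permutations) {
      perms <- permute_all(p$chain_relations)
      lapply(perms, chain_expr)
    } else {
      list(chain_expr(p$chain_relations))
    }
    sup <- do.call(ce_or, c(list(sup), alts))
  }
  list(ax_subclass(ce_named(p$target), sup, provenance = provenance))
}

permute_all <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permute_all(x[-i])) {
      out[[length(out) + 1L]] <- c(x[[i]], rest)
    }
  }
  out
}

#' Proper-parthood definition
#'
#' `x II-proper-part-of y` if and only if `x II-part-of y` and not
#' `y II-part-of x`. The definition is not expressible as a first-order OWL
#' axiom, so it is carried as a pattern annotation and evaluated natively by
#' the model checker; see [proper_part_extension()] for the defined
#' extension.
#'
#' @return List with one pattern axiom.
#' @export
proper_part_axioms <- function() {
  list(ax_pattern("proper-part-def",
                  rel = "II-proper-part-of", base = "II-part-of"))
}

#' Location propagation chains
#'
#' Location propagates along parthood in both compositions: a part of
#' something located at `z` is located at `z`, and something located inside a
#' part of `z` is located at `z`.
#'
#' @return List with the two property-chain axioms
#'   `II-part-of o II-region-of -> II-region-of` and
#'   `II-region-of o II-part-of -> II-region-of`.
#' @export
location_chain_axioms <- function() {
  list(ax_chain(c("II-part-of", "II-region-of"), "II-region-of"),
       ax_chain(c("II-region-of", "II-part-of"), "II-region-of"))
}

#' Mint a class identifier from a surface string
#'
#' Deterministic: trims, collapses every run of non-alphanumeric characters
#' to a single underscore. Used so identical mentions in different documents
#' denote the same class IRI.
#'
#' @param surface surface string.
#' @return Identifier string.
#' @examples
#' mint_class_id("CD19/CD21/CD81/Leu-13 complex")
#' @export
mint_class_id <- function(surface) {
  id <- gsub("[^A-Za-z0-9]+", "_", trimws(surface))
  id <- gsub("^_+|_+$", "", id)
  if (!nzchar(id)) stop("surface ", dQuote(surface), " yields an empty id")
  id
}

#' Group mentions into GGP classes
#'
#' Groups term mentions by equivalence links (merged transitively), plus one
#' singleton group per GGP-typed mention (term class in
#' `map$ggp_term_classes`) not covered by a link. Each group becomes a
#' [ggp_class()]; the group's identifier is `G_` plus the minted id of its
#' shortest surface (ties broken lexicographically), and a DNA-typed member
#' (if any) becomes the seed class.
#'
#' @param a an [abstract_annotation()].
#' @param map a relation map (see [load_relation_map()]).
#' @return List of [ggp_class()] objects, with attribute `term_to_ggp`
#'   (named character vector from term mention id to GGP class id).
#' @export
build_ggp_classes <- function(a, map = default_relation_map()) {
  stopifnot(inherits(a, "ggprel_annotation"))
  t <- a$terms
  groups <- a$equivs
  in_group <- unlist(groups)
  singles <- t$id[t$term_class %in% map$ggp_term_classes &
                    !(t$id %in% in_group)]
  groups <- c(groups, as.list(singles))
  term_to_ggp <- character(0)
  out <- list()
  for (g in groups) {
    rows <- t[match(g, t$id), , drop = FALSE]
    members <- tibble::tibble(
      class_id = vapply(rows$surface, mint_class_id, "", USE.NAMES = FALSE),
      term_class = rows$term_class)
    members <- members[!duplicated(members$class_id), , drop = FALSE]
    surf <- rows$surface[order(nchar(rows$surface), rows$surface)][1L]
    gid <- paste0("G_", mint_class_id(surf))
    seed <- members$class_id[members$term_class == "DNA"]
    seed <- if (length(seed)) seed[[1L]] else NULL
    out[[length(out) + 1L]] <- ggp_class(gid, members, seed_dna_class = seed)
    term_to_ggp[g] <- gid
  }
  attr(out, "term_to_ggp") <- term_to_ggp
  out
}

#' Fixed background axioms of the relation ontology
#'
#' Declarations for every taxonomy relation, sub-property edges, inverse
#' links, characteristic axioms from the flags, the location propagation
#' chains, the proper-parthood definition, and (optionally) the kind
#' disjointness axiom. Emitted by [convert_abstract()] for every document
#' and exported standalone by the taxonomy command.
#'
#' @param tax the relation taxonomy.
#' @param disjointness include `DisjointClasses` over the kinds.
#' @param kinds the kind classes.
#' @return List of axioms.
#' @export
background_axioms <- function(tax = genia_taxonomy(), disjointness = TRUE,
                              kinds = c("DNA", "RNA", "Protein")) {
  ax <- list()
  for (nm in names(tax$specs)) {
    sp <- tax$specs[[nm]]
    ax <- c(ax, list(ax_declaration("objectproperty", nm)))
    if (!is.null(sp$parent)) {
      ax <- c(ax, list(ax_subprop(nm, sp$parent)))
    }
    if (!is.null(sp$inverse_of) && nm < sp$inverse_of) {
      ax <- c(ax, list(ax_inverse(nm, sp$inverse_of)))
    }
    for (fl in sp$flags) {
      ax <- c(ax, list(ax_characteristic(nm, fl)))
    }
  }
  ax <- c(ax, location_chain_axioms(), proper_part_axioms())
  if (disjointness) {
    ax <- c(ax, lapply(kinds, function(k) ax_declaration("class", k)),
            list(do.call(ax_disjoint, as.list(kinds))))
  }
  ax
}

#' Convert an annotated abstract to axioms
#'
#' Translates one standoff-annotated abstract into the axiom IR: class
#' declarations for every mention's denoted class (each a subclass of its
#' term-ontology class), GGP class definitions (through the
#' transcription/translation equivalence where a DNA seed exists, primitively
#' otherwise), one pattern expansion per relation mention according to its
#' mapped formal relation, and the fixed background axioms. Provenance
#' annotations tie each relation-derived axiom to its source R line.
#'
#' Under `schema = "generic"` the component-parthood relation mentions are
#' translated with the generic class-level schema
#' (`C subClassOf some(II-R, D)` on the raw mention classes) instead of the
#' GGP-subclass pattern; this is the schema whose over-generalization the
#' pattern repairs, kept for verification experiments.
#'
#' @param a an [abstract_annotation()].
#' @param tax the relation taxonomy.
#' @param map a relation map (see [load_relation_map()]).
#' @param schema `"pattern"` (default) or `"generic"`.
#' @param disjointness emit `DisjointClasses(DNA, RNA, Protein)` (default
#'   `TRUE`).
#' @param kind_constraints emit the background constraint that no
#'   DNA-domain/region (e.g. a promoter) is a part of a protein complex, when
#'   both classes occur in the document (default `TRUE`).
#' @param background include the fixed background axioms (default `TRUE`).
#' @return Canonically ordered list of axioms (deterministic for identical
#'   input).
#' @export
convert_abstract <- function(a, tax = genia_taxonomy(),
                             map = default_relation_map(),
                             schema = c("pattern", "generic"),
                             disjointness = TRUE, kind_constraints = TRUE,
                             background = TRUE) {
  stopifnot(inherits(a, "ggprel_annotation"))
  schema <- match.arg(schema)
  t <- a$terms
  ax <- list()

  # Mention-denoted classes.
  cls_of <- vapply(t$surface, mint_class_id, "", USE.NAMES = FALSE)
  names(cls_of) <- t$id
  term_classes <- unique(t$term_class)
  for (k in term_classes) ax <- c(ax, list(ax_declaration("class", k)))
  for (i in seq_len(nrow(t))) {
    ax <- c(ax, list(ax_declaration("class", cls_of[[t$id[i]]]),
                     ax_subclass(cls_of[[t$id[i]]], t$term_class[i])))
  }

  # GGP classes.
  ggps <- build_ggp_classes(a, map)
  term_to_ggp <- attr(ggps, "term_to_ggp")
  ax <- c(ax, list(ax_declaration("class", "GGP")))
  for (g in ggps) {
    ax <- c(ax, list(ax_declaration("class", g$id)))
    if (!is.null(g$seed_dna_class)) {
      ax <- c(ax, define_ggp_class(g, tax))
    } else {
      ax <- c(ax, list(ax_subclass(g$id, "GGP")))
    }
    for (m in g$members$class_id) {
      ax <- c(ax, list(ax_subclass(m, g$id)))
    }
  }

  # Relation mentions.
  r <- a$relations
  for (i in seq_len(nrow(r))) {
    lbl <- r$label[i]
    formal <- if (lbl %in% names(map$labels)) map$labels[[lbl]] else NULL
    if (is.null(formal)) {
      stop("document ", a$doc_id, ", relation ", r$id[i],
           ": unmapped relation label '", lbl, "'")
    }
    prov <- paste0(a$doc_id, ":", r$id[i])
    a1 <- r$arg1[i]; a2 <- r$arg2[i]
    c1 <- cls_of[[a1]]; c2 <- cls_of[[a2]]
    g1 <- unname(term_to_ggp[a1]); g2 <- unname(term_to_ggp[a2])

    if (identical(formal, "is-a")) {
      sup <- if (!is.na(g2)) g2 else c2
      ax <- c(ax, convert_subclass_relation(c1, sup, provenance = prov))
      next
    }
    sp <- tax$specs[[formal]]
    if (is.null(sp)) {
      stop("document ", a$doc_id, ", relation ", r$id[i], ": label '", lbl,
           "' maps to unknown relation '", formal, "'")
    }
    component <- formal %in% c("GGP-subclass-has-part", "GGP-subclass-part-of")
    if (schema == "generic" && component) {
      # Generic class-level schema on the raw mention classes.
      prim <- sp$defined_from
      ax <- c(ax, list(ax_subclass(ce_named(c1), ce_some(prim, ce_named(c2)),
                                   provenance = prov)))
      next
    }
    # Anchor the pattern at the GGP-denoting argument.
    if (!is.na(g1)) {
      rel <- formal; ggp <- g1; target <- c2
    } else if (!is.na(g2) && component) {
      rel <- if (formal == "GGP-subclass-has-part") "GGP-subclass-part-of"
             else "GGP-subclass-has-part"
      ggp <- g2; target <- c1
    } else if (component) {
      # Neither argument denotes a GGP: fall back to the generic schema.
      prim <- sp$defined_from
      ax <- c(ax, list(ax_subclass(ce_named(c1), ce_some(prim, ce_named(c2)),
                                   provenance = prov)))
      next
    } else {
      stop("document ", a$doc_id, ", relation ", r$id[i],
           ": neither argument denotes a GGP class for '", formal, "'")
    }
    p <- pattern_instance(ggp, rel, target, kinds = map$kinds)
    if (startsWith(rel, "GGP-subclass-")) {
      ax <- c(ax, expand_subclass_pattern(p, tax, provenance = prov))
    } else {
      ax <- c(ax, expand_variant_pattern(
        p, tax, kind_restrictions = map$kind_restrictions,
        provenance = prov))
    }
  }

  if (background) {
    ax <- c(ax, background_axioms(tax, disjointness = disjointness,
                                  kinds = map$kinds))
  }
  if (kind_constraints &&
      all(c("DNA_domain_or_region", "Protein_complex") %in% term_classes)) {
    ax <- c(ax, list(ax_subclass(
      ce_and(ce_named("DNA_domain_or_region"),
             ce_some("II-part-of", ce_named("Protein_complex"))),
      ce_nothing())))
  }
  # Canonical order, duplicates removed.
  ax <- axiom_sort(ax)
  ax[!duplicated(vapply(ax, axiom_str, ""))]
}
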