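#' Axiom flags
#'
#' The closed set of axiom flags a relation specification may carry.
#' `NON_TRANSITIVE` records a deliberate *non-assertion* of transitivity (the
#' entailment is absent), never intransitivity for all triples; it is kept as
#' an explicit flag so the OWL writer can document the deliberate omission.
#' `STRONG_SUPPLEMENTATION` is the extensional-mereology principle: if every
#' part of y overlaps x, then y is part of x.
#'
#' @return Character vector of flag names.
#' @export
axiom_flags <- function() {
  c("REFLEXIVE", "IRREFLEXIVE", "SYMMETRIC", "ASYMMETRIC", "ANTISYMMETRIC",
    "TRANSITIVE", "NON_TRANSITIVE", "STRONG_SUPPLEMENTATION")
}

#' Create a relation specification
#'
#' One relation of the relation ontology: its level (`II` between individuals,
#' `CC` between classes, `GGP` for relations taking a gene/gene-product class
#' as argument), optional domain/range classes, axiom flags, super-relation,
#' and -- for GGP-level relations -- the II-level primitive its pattern
#' definition expands to.
#'
#' @param name relation identifier (lowercase hyphenated, as used in the
#'   relation ontology).
#' @param level one of `"II"`, `"CC"`, `"GGP"`.
#' @param flags character vector drawn from [axiom_flags()].
#' @param domain_class,range_class optional class identifiers (`NULL` =
#'   unrestricted).
#' @param parent optional identifier of the super-relation.
#' @param defined_from for GGP-level relations, the II-level primitive used by
#'   the relation's pattern definition (mandatory at that level).
#' @param inverse_of optional identifier of the inverse relation.
#' @param kind_restriction for variant sub-relations: the kind class
#'   (`"Protein"`, `"DNA"`, `"RNA"`) the GGP filler is restricted to, or
#'   `NULL` for unrestricted.
#' @return An object of class `ggprel_relspec`.
#' @export
relation_spec <- function(name, level, flags = character(0),
                          domain_class = NULL, range_class = NULL,
                          parent = NULL, defined_from = NULL,
                          inverse_of = NULL, kind_restriction = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            level %in% c("II", "CC", "GGP"),
            all(flags %in% axiom_flags()))
  if (level == "GGP" && is.null(defined_from)) {
    stop("GGP-level relation '", name, "' must carry a defined_from primitive")
  }
  if (all(c("REFLEXIVE", "IRREFLEXIVE") %in% flags)) {
    stop("REFLEXIVE and IRREFLEXIVE may not co-occur on '", name, "'")
  }
  if (all(c("SYMMETRIC", "ASYMMETRIC") %in% flags)) {
    stop("SYMMETRIC and ASYMMETRIC may not co-occur on '", name, "'")
  }
  structure(list(name = name, level = level, flags = sort(unique(flags)),
                 domain_class = domain_class, range_class = range_class,
                 parent = parent, defined_from = defined_from,
                 inverse_of = inverse_of,
                 kind_restriction = kind_restriction),
            class = "ggprel_relspec")
}

#' The shipped relation taxonomy
#'
#' Constructs the complete taxonomy of relations used for gene/gene-product
#' (GGP) annotation: the individual-level mereological primitives
#' (`II-part-of` and its inverse, component-object parthood, proper parthood,
#' membership, location), the variance primitives (`II-has-variant` and its
#' six sub-relations), the transcription/translation relations imported from
#' the Sequence Ontology namespace, the generic class-level schemata
#' (`CC-part-of`, `CC-has-part`), and the GGP-level relations defined through
#' the ontology design patterns.
#'
#' Axiom flags follow the prose characterization: `II-part-of` is reflexive,
#' transitive and antisymmetric; `II-oc-part-of` additionally satisfies strong
#' supplementation; `II-member-of` is irreflexive, asymmetric and
#' non-transitive and a sub-relation of `II-proper-part-of`; `II-has-variant`
#' is reflexive, symmetric and non-transitive; `II-has-mutant` is irreflexive
#' and symmetric (hence non-transitive). `II-has-experimental-material` is
#' declared without axioms.
#'
#' @return An object of class `ggprel_taxonomy`: a list with `specs` (named
#'   list of [relation_spec()] objects) and `roots`.
#' @examples
#' tax <- genia_taxonomy()
#' tax$specs[["II-part-of"]]$flags
#' @export
genia_taxonomy <- function() {
  s <- list(
    # Sequence Ontology derivation primitives (imported namespace).
    relation_spec("transcribed-from", "II"),
    relation_spec("translated-from", "II"),

    # Mereological primitives.
    relation_spec("II-part-of", "II",
                  flags = c("REFLEXIVE", "TRANSITIVE", "ANTISYMMETRIC"),
                  inverse_of = "II-has-part"),
    relation_spec("II-has-part", "II",
                  flags = c("REFLEXIVE", "TRANSITIVE", "ANTISYMMETRIC"),
                  inverse_of = "II-part-of"),
    relation_spec("II-oc-part-of", "II", parent = "II-part-of",
                  flags = c("REFLEXIVE", "TRANSITIVE", "ANTISYMMETRIC",
                            "STRONG_SUPPLEMENTATION")),
    relation_spec("II-proper-part-of", "II", parent = "II-part-of",
                  defined_from = "II-part-of",
                  flags = c("IRREFLEXIVE", "ASYMMETRIC", "TRANSITIVE")),
    relation_spec("II-member-of", "II", parent = "II-proper-part-of",
                  flags = c("IRREFLEXIVE", "ASYMMETRIC", "NON_TRANSITIVE")),
    relation_spec("II-region-of", "II"),

    # Variance primitives.
    relation_spec("II-has-variant", "II",
                  flags = c("REFLEXIVE", "SYMMETRIC", "NON_TRANSITIVE")),
    relation_spec("II-has-isoform", "II", parent = "II-has-variant",
                  flags = "NON_TRANSITIVE"),
    relation_spec("II-has-mutant", "II", parent = "II-has-variant",
                  flags = c("IRREFLEXIVE", "SYMMETRIC", "NON_TRANSITIVE")),
    relation_spec("II-has-recombinant", "II", parent = "II-has-variant",
                  flags = "NON_TRANSITIVE"),
    relation_spec("II-has-precursor", "II", parent = "II-has-variant",
                  flags = "NON_TRANSITIVE"),
    relation_spec("II-has-modified-protein", "II", parent = "II-has-variant",
                  flags = "NON_TRANSITIVE"),
    # Formal characterization deliberately absent (future work): declared only.
    relation_spec("II-has-experimental-material", "II",
                  parent = "II-has-variant"),

    # Generic class-level schemata (C subClassOf some(II-R, D)).
    relation_spec("CC-part-of", "CC"),
    relation_spec("CC-has-part", "CC"),

    # GGP-level relations, defined through the ontology design patterns.
    relation_spec("GGP-subclass-has-part", "GGP",
                  defined_from = "II-has-part"),
    relation_spec("GGP-subclass-part-of", "GGP",
                  defined_from = "II-part-of"),
    relation_spec("GGP-subclass-member-of", "GGP",
                  defined_from = "II-member-of"),
    relation_spec("GGP-subclass-region-of", "GGP",
                  defined_from = "II-region-of"),
    relation_spec("GGP-has-variant", "GGP", defined_from = "II-has-variant"),
    relation_spec("GGP-has-modified-protein", "GGP",
                  parent = "GGP-has-variant",
                  defined_from = "II-has-modified-protein",
                  kind_restriction = "Protein"),
    relation_spec("GGP-has-isoform", "GGP", parent = "GGP-has-variant",
                  defined_from = "II-has-isoform",
                  kind_restriction = "Protein"),
    relation_spec("GGP-has-mutant", "GGP", parent = "GGP-has-variant",
                  defined_from = "II-has-mutant",
                  kind_restriction = "Protein"),
    relation_spec("GGP-has-recombinant", "GGP", parent = "GGP-has-variant",
                  defined_from = "II-has-recombinant",
                  kind_restriction = "DNA"),
    relation_spec("GGP-has-precursor", "GGP", parent = "GGP-has-variant",
                  defined_from = "II-has-precursor",
                  kind_restriction = "Protein"),
    relation_spec("GGP-has-experimental-material", "GGP",
                  parent = "GGP-has-variant",
                  defined_from = "II-has-experimental-material")
  )
  names(s) <- vapply(s, function(x) x$name, "")
  tax <- structure(
    list(specs = s,
         roots = names(s)[vapply(s, function(x) is.null(x$parent), TRUE)]),
    class = "ggprel_taxonomy")
  validate_taxonomy(tax)
  tax
}

validate_taxonomy <- function(tax) {
  specs <- tax$specs
  for (sp in specs) {
    if (!is.null(sp$parent) && is.null(specs[[sp$parent]])) {
      stop("parent '", sp$parent, "' of '", sp$name, "' not in taxonomy")
    }
    if (!is.null(sp$defined_from)) {
      df <- specs[[sp$defined_from]]
      if (is.null(df)) {
        stop("defined_from '", sp$defined_from, "' of '", sp$name,
             "' not in taxonomy")
      }
      if (sp$level == "GGP" && df$level != "II") {
        stop("defined_from of GGP relation '", sp$name,
             "' must be an II-level primitive")
      }
    }
  }
  # parent links must form a forest
  for (nm in names(specs)) {
    seen <- character(0)
    cur <- nm
    while (!is.null(specs[[cur]]$parent)) {
      if (cur %in% seen) stop("parent cycle through '", cur, "'")
      seen <- c(seen, cur)
      cur <- specs[[cur]]$parent
    }
  }
  invisible(tax)
}

#' @export
print.ggprel_taxonomy <- function(x, ...) {
  cat("Relation taxonomy:", length(x$specs), "relations\n")
  show <- function(id, indent) {
    sp <- x$specs[[id]]
    cat(strrep("  ", indent), id,
        if (length(sp$flags)) paste0("  {", paste(sp$flags, collapse = ", "), "}")
        else "",
        if (!is.null(sp$defined_from)) paste0("  <= ", sp$defined_from)
        else "",
        "\n", sep = "")
    kids <- names(x$specs)[vapply(x$specs, function(s)
      identical(s$parent, id), TRUE)]
    for (k in kids) show(k, indent + 1L)
  }
  for (r in x$roots) show(r, 1L)
  invisible(x)
}

#' Tabulate a relation taxonomy
#'
#' @param x a `ggprel_taxonomy`.
#' @param ... unused.
#' @return A tibble with one row per relation (flags collapsed with `";"`).
#' @importFrom tibble as_tibble tibble
#' @method as_tibble ggprel_taxonomy
#' @export
as_tibble.ggprel_taxonomy <- function(x, ...) {
  specs <- x$specs
  tibble::tibble(
    name = names(specs),
    level = vapply(specs, function(s) s$level, ""),
    flags = vapply(specs, function(s) paste(s$flags, collapse = ";"), ""),
    parent = vapply(specs, function(s) s$parent %||% NA_character_, ""),
    defined_from = vapply(specs, function(s) s$defined_from %||% NA_character_, ""),
    inverse_of = vapply(specs, function(s) s$inverse_of %||% NA_character_, ""),
    kind_restriction = vapply(specs, function(s)
      s$kind_restriction %||% NA_character_, "")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a taxonomy as YAML
#'
#' @param tax a `ggprel_taxonomy`.
#' @return A YAML string (identifier, level, flags, parent, defined_from).
#' @export
taxonomy_yaml <- function(tax) {
  out <- lapply(tax$specs, function(s) {
    e <- list(level = s$level, flags = as.list(s$flags))
    if (!is.null(s$parent)) e$parent <- s$parent
    if (!is.null(s$defined_from)) e$defined_from <- s$defined_from
    if (!is.null(s$inverse_of)) e$inverse_of <- s$inverse_of
    if (!is.null(s$kind_restriction)) e$kind_restriction <- s$kind_restriction
    e
  })
  yaml::as.yaml(out)
}

#' Check joint satisfiability of a relation's axiom flags
#'
#' Returns conflict descriptors for a flag set; an empty list means the flags
#' are jointly satisfiable by a *nonempty* relation on a domain of two
#' individuals. Conflicts are data, not errors: contradictory pairs are named,
#' and flag sets that force the relation empty (symmetry plus antisymmetry
#' plus irreflexivity) are reported as `"relation forced empty"`.
#'
#' @param spec a [relation_spec()] or a character vector of flags.
#' @return List of conflicts, each `list(flags = <offending flags>,
#'   reason = <message>)`.
#' @examples
#' validate_flags(genia_taxonomy()$specs[["II-part-of"]])  # list()
#' @export
validate_flags <- function(spec) {
  flags <- if (inherits(spec, "ggprel_relspec")) spec$flags else spec
  stopifnot(all(flags %in% axiom_flags()))
  conflicts <- list()
  add <- function(fl, reason) {
    conflicts[[length(conflicts) + 1L]] <<- list(flags = fl, reason = reason)
  }
  has <- function(f) f %in% flags
  if (has("REFLEXIVE") && has("IRREFLEXIVE")) {
    add(c("REFLEXIVE", "IRREFLEXIVE"),
        "contradictory on any nonempty domain")
  }
  if (has("SYMMETRIC") && has("ASYMMETRIC")) {
    add(c("SYMMETRIC", "ASYMMETRIC"),
        "symmetric and asymmetric force the relation empty and clash with use")
  }
  if (has("REFLEXIVE") && has("ASYMMETRIC")) {
    add(c("REFLEXIVE", "ASYMMETRIC"),
        "asymmetry entails irreflexivity, contradicting reflexivity")
  }
  if (has("TRANSITIVE") && has("NON_TRANSITIVE")) {
    add(c("TRANSITIVE", "NON_TRANSITIVE"),
        "transitivity both asserted and deliberately not asserted")
  }
  if (has("SYMMETRIC") && has("ANTISYMMETRIC") &&
      (has("IRREFLEXIVE") || has("ASYMMETRIC"))) {
    add(c("SYMMETRIC", "ANTISYMMETRIC", "IRREFLEXIVE"),
        "relation forced empty")
  }
  # a nonempty symmetric transitive relation always contains a loop
  if (has("SYMMETRIC") && has("TRANSITIVE") &&
      (has("IRREFLEXIVE") || has("ASYMMETRIC"))) {
    add(c("SYMMETRIC", "TRANSITIVE", "IRREFLEXIVE"),
        "relation forced empty")
  }
  conflicts
}

# ---- taxonomy helpers -------------------------------------------------------

tax_spec <- function(tax, id) {
  sp <- tax$specs[[id]]
  if (is.null(sp)) stop("relation '", id, "' not in taxonomy")
  sp
}

# Ancestors via parent links (nearest first, excluding id itself).
tax_ancestors <- function(tax, id) {
  out <- character(0)
  cur <- tax$specs[[id]]$parent
  while (!is.null(cur)) {
    out <- c(out, cur)
    cur <- tax$specs[[cur]]$parent
  }
  out
}

tax_children <- function(tax, id) {
  names(tax$specs)[vapply(tax$specs, function(s)
    identical(s$parent, id), TRUE)]
}

# Canonical primitive for kind counting: resolve II-has-part to II-part-of
# through the inverse link, so parthood in both directions counts once.
canonical_primitive <- function(tax, id) {
  sp <- tax$specs[[id]]
  if (!is.null(sp$inverse_of) && sp$inverse_of < id) sp$inverse_of else id
}

#' Structural counts of the shipped taxonomy
#'
#' Counts the sub-relations of `GGP-has-variant` (one per variance relation
#' used in the annotation) and the distinct parthood kinds among the
#' `GGP-subclass-*` relations (component parthood, membership, location),
#' where the two directions of component parthood count as one kind.
#'
#' @param tax a `ggprel_taxonomy` (defaults to the shipped one).
#' @return Named list with `n_variant_subrelations` and `n_parthood_kinds`.
#' @export
taxonomy_counts <- function(tax = genia_taxonomy()) {
  variant_subs <- tax_children(tax, "GGP-has-variant")
  subclass_rels <- names(tax$specs)[
    startsWith(names(tax$specs), "GGP-subclass-")]
  prims <- vapply(subclass_rels, function(r)
    canonical_primitive(tax, tax$specs[[r]]$defined_from), "")
  list(n_variant_subrelations = length(variant_subs),
       n_parthood_kinds = length(unique(prims)))
}
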