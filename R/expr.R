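#' @title Class expressions and axioms
#' @description Internal representation (IR) for OWL 2 class expressions and
#'   axioms. Pattern expansions produce these; the OWL writer serializes them
#'   and the finite-model checker evaluates them.
#' @name ggprel-ir
NULL

# ---- class expressions ------------------------------------------------------

new_expr <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "ggprel_expr")
}

#' Class expression constructors
#'
#' Build the class expressions used throughout the package: named classes,
#' intersections, unions, complements, existential restrictions and the
#' top/bottom classes (`owl:Thing` / `owl:Nothing`).
#'
#' @param id class identifier (character scalar).
#' @param ... sub-expressions (or identifiers, coerced via [as_expr()]).
#' @param x a class expression or identifier.
#' @param rel relation identifier; `"owl:topObjectProperty"` denotes the
#'   universal relation.
#' @param filler class expression the restriction quantifies over.
#' @return An object of class `ggprel_expr`.
#' @examples
#' ce_some("II-part-of", ce_named("CD19"))
#' ce_and("DNA", ce_not("Protein"))
#' @export
ce_named <- function(id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  new_expr("named", id = id)
}

#' @rdname ce_named
#' @export
ce_and <- function(...) {
  args <- lapply(list(...), as_expr)
  stopifnot(length(args) >= 2L)
  new_expr("and", args = args)
}

#' @rdname ce_named
#' @export
ce_or <- function(...) {
  args <- lapply(list(...), as_expr)
  stopifnot(length(args) >= 2L)
  new_expr("or", args = args)
}

#' @rdname ce_named
#' @export
ce_not <- function(x) new_expr("not", arg = as_expr(x))

#' @rdname ce_named
#' @export
ce_some <- function(rel, filler) {
  stopifnot(is.character(rel), length(rel) == 1L)
  new_expr("some", rel = rel, filler = as_expr(filler))
}

#' @rdname ce_named
#' @export
ce_nothing <- function() new_expr("nothing")

#' @rdname ce_named
#' @export
ce_thing <- function() new_expr("thing")

#' @rdname ce_named
#' @export
as_expr <- function(x) {
  if (inherits(x, "ggprel_expr")) return(x)
  if (is.character(x) && length(x) == 1L) return(ce_named(x))
  stop("cannot coerce to a class expression: ", deparse(substitute(x)))
}

#' @export
print.ggprel_expr <- function(x, ...) {
  cat("<class expression> ", expr_str(x), "\n", sep = "")
  invisible(x)
}

# Canonical functional-syntax rendering; also the writer's serialization.
expr_str <- function(e) {
  switch(e$kind,
    named   = paste0(":", e$id),
    thing   = "owl:Thing",
    nothing = "owl:Nothing",
    and     = paste0("ObjectIntersectionOf(",
                     paste(vapply(e$args, expr_str, ""), collapse = " "), ")"),
    or      = paste0("ObjectUnionOf(",
                     paste(vapply(e$args, expr_str, ""), collapse = " "), ")"),
    not     = paste0("ObjectComplementOf(", expr_str(e$arg), ")"),
    some    = paste0("ObjectSomeValuesFrom(", rel_str(e$rel), " ",
                     expr_str(e$filler), ")"),
    stop("unknown expression kind: ", e$kind)
  )
}

rel_str <- function(rel) {
  if (rel == "owl:topObjectProperty") rel else paste0(":", rel)
}

# Collect named class / relation identifiers mentioned in an expression.
expr_class_ids <- function(e) {
  switch(e$kind,
    named = e$id,
    and   = unique(unlist(lapply(e$args, expr_class_ids))),
    or    = unique(unlist(lapply(e$args, expr_class_ids))),
    not   = expr_class_ids(e$arg),
    some  = expr_class_ids(e$filler),
    character(0)
  )
}

expr_rel_ids <- function(e) {
  switch(e$kind,
    and  = unique(unlist(lapply(e$args, expr_rel_ids))),
    or   = unique(unlist(lapply(e$args, expr_rel_ids))),
    not  = expr_rel_ids(e$arg),
    some = unique(c(e$rel, expr_rel_ids(e$filler))),
    character(0)
  )
}

# TRUE iff evaluating e is monotone in the class/relation extensions
# (no complement anywhere); closure may only fire on monotone bodies.
expr_monotone <- function(e) {
  switch(e$kind,
    named = TRUE, thing = TRUE, nothing = TRUE,
    and   = all(vapply(e$args, expr_monotone, TRUE)),
    or    = all(vapply(e$args, expr_monotone, TRUE)),
    not   = FALSE,
    some  = expr_monotone(e$filler)
  )
}

# ---- axioms -----------------------------------------------------------------

new_axiom <- function(type, ..., provenance = NULL) {
  structure(list(type = type, ..., provenance = provenance),
            class = "ggprel_axiom")
}

#' Axiom constructors
#'
#' Build axioms of the internal representation. `ax_pattern()` carries a
#' machine-readable ontology-design-pattern annotation together with an
#' optional OWL-encodable form (`encoded`), so the model checker can evaluate
#' the pattern natively while the OWL writer still serializes it.
#'
#' @param sub,sup subclass / superclass (expressions or identifiers); for
#'   `ax_subprop()`, relation identifiers.
#' @param ... expressions (equivalence/disjointness) or named pattern
#'   parameters.
#' @param chain character vector (length >= 2) of relation identifiers.
#' @param rel,rel1,rel2 relation identifiers.
#' @param which axiom-flag name, e.g. `"TRANSITIVE"` (see [axiom_flags()]).
#' @param expr class expression of a class assertion.
#' @param individual,from,to individual identifiers.
#' @param kind,id entity kind (`"class"` or `"objectproperty"`) and identifier.
#' @param subject,text annotation subject identifier and literal text.
#' @param name pattern name (`"subclass-disjunction"`, `"proper-part-def"`,
#'   `"strong-supplementation"`).
#' @param encoded optional OWL-encodable `ggprel_axiom` standing in for the
#'   pattern in serializations.
#' @param provenance optional provenance string (e.g. a standoff R-line id).
#' @return An object of class `ggprel_axiom`.
#' @export
ax_subclass <- function(sub, sup, provenance = NULL) {
  new_axiom("subclass", sub = as_expr(sub), sup = as_expr(sup),
            provenance = provenance)
}

#' @rdname ax_subclass
#' @export
ax_equivalent <- function(..., provenance = NULL) {
  exprs <- lapply(list(...), as_expr)
  stopifnot(length(exprs) >= 2L)
  new_axiom("equivalent", exprs = exprs, provenance = provenance)
}

#' @rdname ax_subclass
#' @export
ax_disjoint <- function(..., provenance = NULL) {
  exprs <- lapply(list(...), as_expr)
  stopifnot(length(exprs) >= 2L)
  new_axiom("disjoint", exprs = exprs, provenance = provenance)
}

#' @rdname ax_subclass
#' @export
ax_subprop <- function(sub, sup, provenance = NULL) {
  new_axiom("subprop", sub = sub, sup = sup, provenance = provenance)
}

#' @rdname ax_subclass
#' @export
ax_chain <- function(chain, sup, provenance = NULL) {
  stopifnot(length(chain) >= 2L)
  new_axiom("chain", chain = chain, sup = sup, provenance = provenance)
}

#' @rdname ax_subclass
#' @export
ax_inverse <- function(rel1, rel2, provenance = NULL) {
  new_axiom("inverse", rel1 = rel1, rel2 = rel2, provenance = provenance)
}

#' @rdname ax_subclass
#' @export
ax_characteristic <- function(rel, which, provenance = NULL) {
  stopifnot(which %in% axiom_flags())
  new_axiom("characteristic", rel = rel, which = which,
            provenance = provenance)
}

#' @rdname ax_subclass
#' @export
ax_class_assertion <- function(expr, individual, provenance = NULL) {
  new_axiom("class_assertion", expr = as_expr(expr), individual = individual,
            provenance = provenance)
}

#' @rdname ax_subclass
#' @export
ax_prop_assertion <- function(rel, from, to, provenance = NULL) {
  new_axiom("prop_assertion", rel = rel, from = from, to = to,
            provenance = provenance)
}

#' @rdname ax_subclass
#' @export
ax_declaration <- function(kind, id, provenance = NULL) {
  stopifnot(kind %in% c("class", "objectproperty"))
  new_axiom("declaration", kind = kind, id = id, provenance = provenance)
}

#' @rdname ax_subclass
#' @export
ax_annotation <- function(subject, text, provenance = NULL) {
  new_axiom("annotation", subject = subject, text = text,
            provenance = provenance)
}

#' @rdname ax_subclass
#' @export
ax_pattern <- function(name, ..., encoded = NULL, provenance = NULL) {
  new_axiom("pattern", pattern = c(list(name = name), list(...)),
            encoded = encoded, provenance = provenance)
}

#' @export
print.ggprel_axiom <- function(x, ...) {
  cat("<axiom> ", axiom_str(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.ggprel_axiom <- function(x, ...) axiom_str(x)

# Pattern parameters serialized as "key=v1,v2|key2=..." in canonical key
# order, so reconstructed pattern axioms render identically.
pattern_key_order <- c("ggp", "relation", "primitive", "target", "kinds",
                       "rel", "base")

pattern_param_str <- function(p) {
  keys <- setdiff(names(p), "name")
  keys <- c(intersect(pattern_key_order, keys),
            sort(setdiff(keys, pattern_key_order)))
  paste(vapply(keys, function(k) {
    paste0(k, "=", paste(p[[k]], collapse = ","))
  }, ""), collapse = "|")
}

# Canonical one-line rendering of an axiom; this IS the functional-syntax
# serialization (modulo provenance annotations added by the writer).
axiom_str <- function(ax) {
  s <- switch(ax$type,
    declaration = paste0("Declaration(",
      if (ax$kind == "class") "Class" else "ObjectProperty",
      "(:", ax$id, "))"),
    subclass   = paste0("SubClassOf(", expr_str(ax$sub), " ",
                        expr_str(ax$sup), ")"),
    equivalent = paste0("EquivalentClasses(",
                        paste(vapply(ax$exprs, expr_str, ""), collapse = " "),
                        ")"),
    disjoint   = paste0("DisjointClasses(",
                        paste(vapply(ax$exprs, expr_str, ""), collapse = " "),
                        ")"),
    subprop    = paste0("SubObjectPropertyOf(", rel_str(ax$sub), " ",
                        rel_str(ax$sup), ")"),
    chain      = paste0("SubObjectPropertyOf(ObjectPropertyChain(",
                        paste(vapply(ax$chain, rel_str, ""), collapse = " "),
                        ") ", rel_str(ax$sup), ")"),
    inverse    = paste0("InverseObjectProperties(", rel_str(ax$rel1), " ",
                        rel_str(ax$rel2), ")"),
    characteristic = {
      fn <- c(REFLEXIVE = "ReflexiveObjectProperty",
              IRREFLEXIVE = "IrreflexiveObjectProperty",
              SYMMETRIC = "SymmetricObjectProperty",
              ASYMMETRIC = "AsymmetricObjectProperty",
              TRANSITIVE = "TransitiveObjectProperty")[ax$which]
      if (is.na(fn)) {
        # ANTISYMMETRIC / NON_TRANSITIVE / STRONG_SUPPLEMENTATION are not
        # OWL 2 constructs; canonical form is a tagged annotation.
        paste0("AnnotationAssertion(rdfs:comment ", rel_str(ax$rel),
               " \"ggprel-characteristic: ", ax$which, "\")")
      } else {
        paste0(fn, "(", rel_str(ax$rel), ")")
      }
    },
    class_assertion = paste0("ClassAssertion(", expr_str(ax$expr), " :",
                             ax$individual, ")"),
    prop_assertion  = paste0("ObjectPropertyAssertion(", rel_str(ax$rel),
                             " :", ax$from, " :", ax$to, ")"),
    annotation = paste0("AnnotationAssertion(rdfs:comment :", ax$subject,
                        " ", fss_quote(ax$text), ")"),
    pattern    = paste0("ggprel-pattern: ", ax$pattern$name, "|",
                        pattern_param_str(ax$pattern)),
    stop("unknown axiom type: ", ax$type)
  )
  s
}

fss_quote <- function(x) {
  paste0("\"", gsub("\"", "\\\\\"", gsub("\\\\", "\\\\\\\\", x)), "\"")
}

# Relation / class identifiers an axiom mentions (used by the writer's
# simplicity analysis and the fixtures coverage test).
axiom_rel_ids <- function(ax) {
  unique(switch(ax$type,
    subclass   = c(expr_rel_ids(ax$sub), expr_rel_ids(ax$sup)),
    equivalent = unlist(lapply(ax$exprs, expr_rel_ids)),
    disjoint   = unlist(lapply(ax$exprs, expr_rel_ids)),
    subprop    = c(ax$sub, ax$sup),
    chain      = c(ax$chain, ax$sup),
    inverse    = c(ax$rel1, ax$rel2),
    characteristic = ax$rel,
    prop_assertion = ax$rel,
    class_assertion = expr_rel_ids(ax$expr),
    declaration = if (ax$kind == "objectproperty") ax$id else character(0),
    pattern    = {
      p <- ax$pattern
      c(p$relation, p$primitive, p$rel, p$base,
        if (!is.null(ax$encoded)) axiom_rel_ids(ax$encoded))
    },
    character(0)
  ))
}

axiom_class_ids <- function(ax) {
  unique(switch(ax$type,
    subclass   = c(expr_class_ids(ax$sub), expr_class_ids(ax$sup)),
    equivalent = unlist(lapply(ax$exprs, expr_class_ids)),
    disjoint   = unlist(lapply(ax$exprs, expr_class_ids)),
    class_assertion = expr_class_ids(ax$expr),
    declaration = if (ax$kind == "class") ax$id else character(0),
    pattern    = {
      p <- ax$pattern
      c(p$ggp, p$target, p$kinds,
        if (!is.null(ax$encoded)) axiom_class_ids(ax$encoded))
    },
    character(0)
  ))
}

# Canonical ordering: declarations, property axioms, class axioms,
# assertions, annotations, patterns -- each block sorted by rendering.
axiom_sort <- function(axioms) {
  if (length(axioms) == 0L) return(axioms)
  rank <- vapply(axioms, function(a) {
    switch(a$type,
      declaration = 0L, subprop = 1L, chain = 1L, inverse = 1L,
      characteristic = 2L, subclass = 3L, equivalent = 3L, disjoint = 3L,
      class_assertion = 4L, prop_assertion = 4L,
      annotation = 5L, pattern = 6L, 7L)
  }, 0L)
  keys <- vapply(axioms, axiom_str, "")
  axioms[order(rank, keys, method = "radix")]
}

axiom_set_equal <- function(a, b) {
  setequal(vapply(a, axiom_str, ""), vapply(b, axiom_str, ""))
}
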