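#' OWL output configuration
#'
#' IRIs and import settings for ontology serialization. With `stub = TRUE`
#' (the default) the imports reference the small stub ontology shipped with
#' the package -- declaring the term-ontology classes (DNA, RNA, Protein,
#' Protein_family_or_group, Protein_complex, DNA_domain_or_region) and the
#' Sequence Ontology derivation relations (transcribed-from,
#' translated-from) -- so nothing is fetched from the network; with
#' `stub = FALSE` they reference the remote Sequence Ontology and term
#' ontology IRIs.
#'
#' @param base_iri base IRI for minted entities.
#' @param ontology_iri ontology IRI (defaults to `base_iri`).
#' @param so_iri,genia_iri remote import IRIs.
#' @param stub use the in-repo stub import instead of the remote IRIs.
#' @return A list of class `ggprel_owl_config`.
#' @export
owl_config <- function(base_iri = "http://example.org/ggprel/onto#",
                       ontology_iri = "http://example.org/ggprel/onto",
                       so_iri = "http://purl.obolibrary.org/obo/so.owl",
                       genia_iri = "http://example.org/genia-term-ontology.owl",
                       stub = TRUE) {
  structure(list(base_iri = base_iri, ontology_iri = ontology_iri,
                 so_iri = so_iri, genia_iri = genia_iri, stub = stub),
            class = "ggprel_owl_config")
}

# Non-simple object properties: declared transitive or conclusion of a
# property chain, propagated up through sub-property edges and across
# inverse links (OWL 2 DL bars some characteristics on these).
nonsimple_properties <- function(axioms) {
  ns <- character(0)
  subprop <- list(); inv <- list()
  for (ax in axioms) {
    if (ax$type == "characteristic" && ax$which == "TRANSITIVE") {
      ns <- c(ns, ax$rel)
    } else if (ax$type == "chain") {
      ns <- c(ns, ax$sup)
    } else if (ax$type == "subprop") {
      subprop[[length(subprop) + 1L]] <- c(ax$sub, ax$sup)
    } else if (ax$type == "inverse") {
      inv[[length(inv) + 1L]] <- c(ax$rel1, ax$rel2)
    }
  }
  repeat {
    added <- FALSE
    for (sp in subprop) {
      if (sp[[1L]] %in% ns && !sp[[2L]] %in% ns) {
        ns <- c(ns, sp[[2L]]); added <- TRUE
      }
    }
    for (iv in inv) {
      if (iv[[1L]] %in% ns && !iv[[2L]] %in% ns) {
        ns <- c(ns, iv[[2L]]); added <- TRUE
      }
      if (iv[[2L]] %in% ns && !iv[[1L]] %in% ns) {
        ns <- c(ns, iv[[1L]]); added <- TRUE
      }
    }
    if (!added) break
  }
  unique(ns)
}

RESTRICTED_CHARACTERISTICS <- c("REFLEXIVE", "IRREFLEXIVE", "SYMMETRIC",
                                "ASYMMETRIC")

#' Serialize axioms to OWL 2 functional syntax
#'
#' Emits a byte-deterministic OWL 2 functional-syntax document: prefix
#' declarations, the ontology header with its imports, the declaration of
#' the `GGP` class, and the axioms in canonical order. Reflexivity,
#' irreflexivity, symmetry and asymmetry characteristics on *non-simple*
#' properties (those occurring as a property-chain conclusion or declared
#' transitive, closed under super-properties and inverses) are not permitted
#' in OWL 2 DL and are dropped from the output, each recorded as an
#' annotation comment instead. Pattern axioms are emitted through their OWL
#' encoding (or, where no first-order encoding exists, as an annotation),
#' tagged with a machine-readable pattern comment so [parse_ontology()] can
#' reconstruct them.
#'
#' @param axioms list of axioms.
#' @param cfg an [owl_config()].
#' @return The document as a single string.
#' @export
write_ontology <- function(axioms, cfg = owl_config()) {
  ns <- nonsimple_properties(axioms)
  axioms <- axiom_sort(axioms)
  axioms <- axioms[!duplicated(vapply(axioms, axiom_str, ""))]
  body <- character(0)
  for (ax in axioms) {
    body <- c(body, render_axiom_fss(ax, ns))
  }
  body <- unique(body[nzchar(body)])
  imports <- if (isTRUE(cfg$stub)) {
    paste0(cfg$ontology_iri, "/so-genia-stub")
  } else {
    c(cfg$so_iri, cfg$genia_iri)
  }
  header <- c(
    paste0("Prefix(:=<", cfg$base_iri, ">)"),
    "Prefix(owl:=<http://www.w3.org/2002/07/owl#>)",
    "Prefix(rdf:=<http://www.w3.org/1999/02/22-rdf-syntax-ns#>)",
    "Prefix(rdfs:=<http://www.w3.org/2000/01/rdf-schema#>)",
    "Prefix(xsd:=<http://www.w3.org/2001/XMLSchema#>)",
    "",
    paste0("Ontology(<", cfg$ontology_iri, ">"),
    paste0("Import(<", imports, ">)"),
    "Declaration(Class(:GGP))")
  body <- setdiff(body, "Declaration(Class(:GGP))")
  paste(c(header, body, ")", ""), collapse = "\n")
}

# One functional-syntax line per axiom (possibly an annotation stand-in for
# constructs OWL 2 cannot express, or empty when fully dropped).
render_axiom_fss <- function(ax, nonsimple = character(0)) {
  annot <- if (!is.null(ax$provenance)) {
    paste0("Annotation(rdfs:comment ", fss_quote(
      paste0("ggprel-src: ", ax$provenance)), ") ")
  } else {
    ""
  }
  inject <- function(s) {
    if (!nzchar(annot)) return(s)
    if (ax$type %in% c("annotation", "declaration")) return(s)
    sub("\\(", paste0("(", annot), s)
  }
  if (ax$type == "characteristic") {
    if (ax$which %in% RESTRICTED_CHARACTERISTICS && ax$rel %in% nonsimple) {
      return(paste0("AnnotationAssertion(rdfs:comment :", ax$rel, " ",
                    fss_quote(paste0("ggprel-omitted-characteristic: ",
                                     ax$which, " (non-simple property)")),
                    ")"))
    }
    return(axiom_str(ax))  # OWL characteristic or tagged annotation form
  }
  if (ax$type == "pattern") {
    tag <- axiom_str(ax)  # "ggprel-pattern: name|params"
    if (!is.null(ax$encoded)) {
      enc <- ax$encoded
      s <- axiom_str(enc)
      note <- paste0("Annotation(rdfs:comment ", fss_quote(tag), ") ", annot)
      return(sub("\\(", paste0("(", note), s))
    }
    subj <- ax$pattern$rel %||% ax$pattern$relation %||% "GGP"
    return(paste0("AnnotationAssertion(rdfs:comment :", subj, " ",
                  fss_quote(tag), ")"))
  }
  inject(axiom_str(ax))
}

#' Write ontology files
#'
#' Serializes one converted abstract to `<doc_id>.ofn` (functional syntax)
#' or `<doc_id>.ttl` (Turtle).
#'
#' @param axioms list of axioms.
#' @param path output file path.
#' @param format `"ofn"` or `"ttl"`.
#' @param cfg an [owl_config()].
#' @return `path`, invisibly.
#' @export
write_ontology_file <- function(axioms, path, format = c("ofn", "ttl"),
                                cfg = owl_config()) {
  format <- match.arg(format)
  doc <- if (format == "ofn") write_ontology(axioms, cfg) else
    write_turtle(axioms, cfg)
  writeLines(doc, path, useBytes = TRUE, sep = "")
  invisible(path)
}

# ---- functional-syntax parser ----------------------------------------------

#' Parse OWL functional syntax (emitted dialect)
#'
#' Inverse of [write_ontology()] on its own output: parses the
#' functional-syntax dialect this package emits back into the axiom IR.
#' Pattern-tagged axioms are reconstructed as pattern axioms; omission
#' comments for dropped characteristics are discarded (the round trip is
#' identity modulo dropped characteristics and canonical ordering).
#' Constructs outside the emitted dialect raise an "out of dialect" error
#' with the character position.
#'
#' @param text a functional-syntax document (string).
#' @return List of axioms.
#' @export
parse_ontology <- function(text) {
  toks <- fss_tokenize(text)
  pos <- 1L
  peek <- function() if (pos <= nrow(toks)) toks$val[pos] else NA_character_
  peek_type <- function() if (pos <= nrow(toks)) toks$type[pos] else "eof"
  advance <- function() {
    v <- toks$val[pos]; pos <<- pos + 1L; v
  }
  fail <- function(msg) {
    at <- if (pos <= nrow(toks)) toks$at[pos] else nchar(text)
    stop("parse error at character ", at, ": ", msg)
  }
  expect <- function(v) {
    if (!identical(peek(), v)) fail(paste0("expected '", v, "', found '",
                                           peek(), "'"))
    advance()
  }

  name_of <- function(tok) sub(":", "", tok, fixed = TRUE)

  parse_expr <- function() {
    t <- peek()
    if (peek_type() == "pname") {
      advance()
      if (t == "owl:Thing") return(ce_thing())
      if (t == "owl:Nothing") return(ce_nothing())
      if (startsWith(t, ":")) return(ce_named(name_of(t)))
      fail(paste0("out of dialect: class ", t))
    }
    kw <- advance(); expect("(")
    out <- switch(kw,
      ObjectIntersectionOf = {
        args <- list()
        while (!identical(peek(), ")")) args <- c(args, list(parse_expr()))
        do.call(ce_and, args)
      },
      ObjectUnionOf = {
        args <- list()
        while (!identical(peek(), ")")) args <- c(args, list(parse_expr()))
        do.call(ce_or, args)
      },
      ObjectComplementOf = ce_not(parse_expr()),
      ObjectSomeValuesFrom = {
        r <- advance()
        rel <- if (r == "owl:topObjectProperty") r else name_of(r)
        ce_some(rel, parse_expr())
      },
      fail(paste0("out of dialect: ", kw)))
    expect(")")
    out
  }

  parse_annotations <- function() {
    out <- character(0)
    while (identical(peek(), "Annotation")) {
      advance(); expect("("); expect("rdfs:comment")
      out <- c(out, advance())  # string literal (already unescaped)
      expect(")")
    }
    out
  }

  wrap_annotated <- function(ax, annots) {
    pat <- annots[startsWith(annots, "ggprel-pattern: ")]
    src <- annots[startsWith(annots, "ggprel-src: ")]
    if (length(src)) ax$provenance <- sub("^ggprel-src: ", "", src[[1L]])
    if (length(pat)) {
      p <- parse_pattern_tag(pat[[1L]])
      ax2 <- do.call(ax_pattern, c(list(name = p$name), p$params,
                                   list(encoded = ax,
                                        provenance = ax$provenance)))
      return(ax2)
    }
    ax
  }

  axioms <- list()
  emit <- function(ax) axioms[[length(axioms) + 1L]] <<- ax

  while (pos <= nrow(toks)) {
    t <- peek()
    if (t %in% c(")",  "")) { advance(); next }
    if (peek_type() == "pname") fail(paste0("unexpected token ", t))
    kw <- advance()
    if (kw == "Prefix") {
      expect("("); advance(); expect(")")  # pname=<iri> collapsed by lexer
      next
    }
    if (kw == "Ontology") { expect("("); advance(); next }
    if (kw == "Import") { expect("("); advance(); expect(")"); next }
    expect("(")
    annots <- parse_annotations()
    if (kw == "Declaration") {
      ent <- advance(); expect("(")
      id <- name_of(advance()); expect(")")
      emit(ax_declaration(
        if (ent == "Class") "class" else "objectproperty", id))
    } else if (kw == "SubClassOf") {
      ax <- ax_subclass(parse_expr(), parse_expr())
      emit(wrap_annotated(ax, annots))
    } else if (kw %in% c("EquivalentClasses", "DisjointClasses")) {
      args <- list()
      while (!identical(peek(), ")")) args <- c(args, list(parse_expr()))
      ax <- do.call(if (kw == "EquivalentClasses") ax_equivalent else
                      ax_disjoint, args)
      emit(wrap_annotated(ax, annots))
    } else if (kw == "SubObjectPropertyOf") {
      if (identical(peek(), "ObjectPropertyChain")) {
        advance(); expect("(")
        chain <- character(0)
        while (!identical(peek(), ")")) chain <- c(chain, name_of(advance()))
        expect(")")
        emit(ax_chain(chain, name_of(advance())))
      } else {
        emit(ax_subprop(name_of(advance()), name_of(advance())))
      }
    } else if (kw == "InverseObjectProperties") {
      emit(ax_inverse(name_of(advance()), name_of(advance())))
    } else if (kw %in% c("TransitiveObjectProperty", "SymmetricObjectProperty",
                         "AsymmetricObjectProperty", "ReflexiveObjectProperty",
                         "IrreflexiveObjectProperty")) {
      which <- c(TransitiveObjectProperty = "TRANSITIVE",
                 SymmetricObjectProperty = "SYMMETRIC",
                 AsymmetricObjectProperty = "ASYMMETRIC",
                 ReflexiveObjectProperty = "REFLEXIVE",
                 IrreflexiveObjectProperty = "IRREFLEXIVE")[[kw]]
      emit(ax_characteristic(name_of(advance()), which))
    } else if (kw == "ClassAssertion") {
      e <- parse_expr()
      emit(ax_class_assertion(e, name_of(advance())))
    } else if (kw == "ObjectPropertyAssertion") {
      emit(ax_prop_assertion(name_of(advance()), name_of(advance()),
                             name_of(advance())))
    } else if (kw == "AnnotationAssertion") {
      expect("rdfs:comment")
      subj <- name_of(advance())
      lit <- advance()
      if (startsWith(lit, "ggprel-characteristic: ")) {
        emit(ax_characteristic(subj,
                               sub("^ggprel-characteristic: ", "", lit)))
      } else if (startsWith(lit, "ggprel-pattern: ")) {
        p <- parse_pattern_tag(lit)
        emit(do.call(ax_pattern, c(list(name = p$name), p$params)))
      } else if (startsWith(lit, "ggprel-omitted-characteristic: ")) {
        # dropped on purpose; not reconstructed
      } else {
        emit(ax_annotation(subj, lit))
      }
    } else {
      fail(paste0("out of dialect: ", kw))
    }
    expect(")")
  }
  axioms
}

parse_pattern_tag <- function(lit) {
  body <- sub("^ggprel-pattern: ", "", lit)
  parts <- strsplit(body, "|", fixed = TRUE)[[1L]]
  name <- parts[[1L]]
  params <- list()
  for (kv in parts[-1L]) {
    eq <- regexpr("=", kv, fixed = TRUE)
    key <- substr(kv, 1L, eq - 1L)
    val <- strsplit(substr(kv, eq + 1L, nchar(kv)), ",", fixed = TRUE)[[1L]]
    params[[key]] <- val
  }
  list(name = name, params = params)
}

# Lexer: IRIs, string literals, prefixed names, keywords, parentheses.
fss_tokenize <- function(text) {
  n <- nchar(text)
  vals <- character(0); types <- character(0); ats <- integer(0)
  i <- 1L
  push <- function(v, t, at) {
    vals[length(vals) + 1L] <<- v
    types[length(types) + 1L] <<- t
    ats[length(ats) + 1L] <<- at
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(") { push("(", "punct", i); i <- i + 1L; next }
    if (ch == ")") { push(")", "punct", i); i <- i + 1L; next }
    if (ch == "\"") {
      j <- i + 1L; out <- character(0)
      while (j <= n) {
        cj <- substr(text, j, j)
        if (cj == "\\") {
          out <- c(out, substr(text, j + 1L, j + 1L)); j <- j + 2L
        } else if (cj == "\"") {
          break
        } else {
          out <- c(out, cj); j <- j + 1L
        }
      }
      if (j > n) stop("parse error at character ", i,
                      ": unterminated string literal")
      push(paste(out, collapse = ""), "string", i)
      i <- j + 1L
      next
    }
    if (ch == "<") {
      j <- regexpr(">", substr(text, i, n), fixed = TRUE)
      if (j < 0L) stop("parse error at character ", i, ": unterminated IRI")
      push(substr(text, i, i + j - 1L), "iri", i)
      i <- i + j
      next
    }
    # name: keyword, prefixed name, or pname=<iri> prefix binding
    m <- regexpr("^[A-Za-z0-9_:][A-Za-z0-9_:.\\-]*(=<[^>]*>)?",
                 substr(text, i, n))
    len <- attr(m, "match.length")
    if (len <= 0L) stop("parse error at character ", i,
                        ": unexpected character '", ch, "'")
    tok <- substr(text, i, i + len - 1L)
    type <- if (grepl("=", tok, fixed = TRUE)) {
      "binding"
    } else if (grepl(":", tok, fixed = TRUE) || startsWith(tok, ":")) {
      "pname"
    } else {
      "name"
    }
    push(tok, type, i)
    i <- i + len
    next
  }
  data.frame(val = vals, type = types, at = ats, stringsAsFactors = FALSE)
}

# ---- Turtle (secondary serialization) ---------------------------------------

#' Serialize axioms to Turtle
#'
#' Secondary, write-only serialization of the same axiom set as
#' [write_ontology()], with class expressions as blank nodes. Applies the
#' same non-simple-characteristic omission rule. Deterministic for identical
#' input.
#'
#' @param axioms list of axioms.
#' @param cfg an [owl_config()].
#' @return The Turtle document as a single string.
#' @export
write_turtle <- function(axioms, cfg = owl_config()) {
  ns <- nonsimple_properties(axioms)
  axioms <- axiom_sort(axioms)
  axioms <- axioms[!duplicated(vapply(axioms, axiom_str, ""))]
  ttl_quote <- function(x) fss_quote(x)
  prop <- function(r) if (r == "owl:topObjectProperty") r else paste0(":", r)
  expr_ttl <- function(e) {
    switch(e$kind,
      named = paste0(":", e$id),
      thing = "owl:Thing",
      nothing = "owl:Nothing",
      and = paste0("[ a owl:Class ; owl:intersectionOf ( ",
                   paste(vapply(e$args, expr_ttl, ""), collapse = " "),
                   " ) ]"),
      or = paste0("[ a owl:Class ; owl:unionOf ( ",
                  paste(vapply(e$args, expr_ttl, ""), collapse = " "),
                  " ) ]"),
      not = paste0("[ a owl:Class ; owl:complementOf ", expr_ttl(e$arg),
                   " ]"),
      some = paste0("[ a owl:Restriction ; owl:onProperty ", prop(e$rel),
                    " ; owl:someValuesFrom ", expr_ttl(e$filler), " ]"))
  }
  lines <- character(0)
  say <- function(...) lines[length(lines) + 1L] <<- paste0(...)
  for (ax in axioms) {
    switch(ax$type,
      declaration = say(":", ax$id, " a ",
                        if (ax$kind == "class") "owl:Class"
                        else "owl:ObjectProperty", " ."),
      subclass = say(expr_ttl(ax$sub), " rdfs:subClassOf ",
                     expr_ttl(ax$sup), " ."),
      equivalent = {
        first <- expr_ttl(ax$exprs[[1L]])
        for (e in ax$exprs[-1L]) {
          say(first, " owl:equivalentClass ", expr_ttl(e), " .")
        }
      },
      disjoint = {
        for (i in seq_along(ax$exprs)) {
          for (j in seq_along(ax$exprs)) {
            if (j <= i) next
            say(expr_ttl(ax$exprs[[i]]), " owl:disjointWith ",
                expr_ttl(ax$exprs[[j]]), " .")
          }
        }
      },
      subprop = say(":", ax$sub, " rdfs:subPropertyOf :", ax$sup, " ."),
      chain = say(":", ax$sup, " owl:propertyChainAxiom ( ",
                  paste(vapply(ax$chain, prop, ""), collapse = " "), " ) ."),
      inverse = say(":", ax$rel1, " owl:inverseOf :", ax$rel2, " ."),
      characteristic = {
        cls <- c(REFLEXIVE = "owl:ReflexiveProperty",
                 IRREFLEXIVE = "owl:IrreflexiveProperty",
                 SYMMETRIC = "owl:SymmetricProperty",
                 ASYMMETRIC = "owl:AsymmetricProperty",
                 TRANSITIVE = "owl:TransitiveProperty")[ax$which]
        if (is.na(cls)) {
          say(":", ax$rel, " rdfs:comment ",
              ttl_quote(paste0("ggprel-characteristic: ", ax$which)), " .")
        } else if (ax$which %in% RESTRICTED_CHARACTERISTICS &&
                   ax$rel %in% ns) {
          say(":", ax$rel, " rdfs:comment ",
              ttl_quote(paste0("ggprel-omitted-characteristic: ", ax$which,
                               " (non-simple property)")), " .")
        } else {
          say(":", ax$rel, " a ", cls, " .")
        }
      },
      class_assertion = say(":", ax$individual, " a ", expr_ttl(ax$expr),
                            " ."),
      prop_assertion = say(":", ax$from, " :", ax$rel, " :", ax$to, " ."),
      annotation = say(":", ax$subject, " rdfs:comment ",
                       ttl_quote(ax$text), " ."),
      pattern = {
        if (!is.null(ax$encoded) && ax$encoded$type == "subclass") {
          say(expr_ttl(ax$encoded$sub), " rdfs:subClassOf ",
              expr_ttl(ax$encoded$sup), " .")
        }
        subj <- ax$pattern$rel %||% ax$pattern$relation %||% "GGP"
        say(":", subj, " rdfs:comment ", ttl_quote(axiom_str(ax)), " .")
      })
  }
  imports <- if (isTRUE(cfg$stub)) {
    paste0("<", cfg$ontology_iri, "/so-genia-stub>")
  } else {
    paste0("<", c(cfg$so_iri, cfg$genia_iri), ">")
  }
  header <- c(
    paste0("@prefix : <", cfg$base_iri, "> ."),
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "",
    paste0("<", cfg$ontology_iri, "> a owl:Ontology ;"),
    paste0("  owl:imports ", paste(imports, collapse = ", "), " ."),
    ":GGP a owl:Class .")
  lines <- setdiff(unique(lines), ":GGP a owl:Class .")
  paste(c(header, lines, ""), collapse = "\n")
}
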