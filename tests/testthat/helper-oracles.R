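# Independent oracles for property tests. Everything here re-implements the
# checked semantics with plain loops and full recomputation, deliberately
# sharing no code path with the package internals it verifies.

PAIR_SEP <- "\x1f"
okey <- function(x, y) paste(x, y, sep = PAIR_SEP)

opairs <- function(m, rel) {
  p <- m$rel_ext[[rel]]
  if (is.null(p)) matrix(character(0), ncol = 2L) else p
}
oclass <- function(m, id) {
  e <- m$class_ext[[id]]
  if (is.null(e)) character(0) else e
}
okeys <- function(m, rel) {
  p <- opairs(m, rel)
  if (nrow(p) == 0L) character(0) else okey(p[, 1L], p[, 2L])
}
oholds <- function(m, rel, x, y) okey(x, y) %in% okeys(m, rel)

# Direct recursive FOL evaluation of a class expression (no eval_expr).
fol_eval <- function(e, m) {
  if (is.character(e)) e <- ce_named(e)
  if (e$kind == "named") return(oclass(m, e$id))
  if (e$kind == "thing") return(m$individuals)
  if (e$kind == "nothing") return(character(0))
  if (e$kind == "not") {
    inside <- fol_eval(e$arg, m)
    return(m$individuals[!(m$individuals %in% inside)])
  }
  if (e$kind %in% c("and", "or")) {
    exts <- lapply(e$args, fol_eval, m = m)
    keep <- character(0)
    for (x in m$individuals) {
      ins <- vapply(exts, function(s) x %in% s, TRUE)
      if ((e$kind == "and" && all(ins)) || (e$kind == "or" && any(ins))) {
        keep <- c(keep, x)
      }
    }
    return(keep)
  }
  if (e$kind == "some") {
    filler <- fol_eval(e$filler, m)
    keep <- character(0)
    for (x in m$individuals) {
      found <- FALSE
      for (y in m$individuals) {
        linked <- if (e$rel == "owl:topObjectProperty") TRUE else
          oholds(m, e$rel, x, y)
        if (linked && y %in% filler) { found <- TRUE; break }
      }
      if (found) keep <- c(keep, x)
    }
    return(keep)
  }
  stop("fol_eval: unknown kind ", e$kind)
}

# Naive fixpoint: full passes, complete recomputation of every rule until
# nothing changes.
naive_closure <- function(m, axioms, tax = NULL) {
  sym <- character(0); trans <- character(0)
  subp <- list(); chains <- list(); inv <- list(); crules <- list()
  for (ax in axioms) {
    if (ax$type == "characteristic" && ax$which == "SYMMETRIC") {
      sym <- c(sym, ax$rel)
    }
    if (ax$type == "characteristic" && ax$which == "TRANSITIVE") {
      trans <- c(trans, ax$rel)
    }
    if (ax$type == "subprop") subp[[length(subp) + 1L]] <- c(ax$sub, ax$sup)
    if (ax$type == "chain") chains[[length(chains) + 1L]] <- ax
    if (ax$type == "inverse") inv[[length(inv) + 1L]] <- c(ax$rel1, ax$rel2)
    if (ax$type == "subclass" && ax$sup$kind == "named" &&
        expr_is_monotone_oracle(ax$sub)) {
      crules[[length(crules) + 1L]] <- list(lhs = ax$sub, rhs = ax$sup$id)
    }
    if (ax$type == "equivalent") {
      for (i in seq_along(ax$exprs)) {
        if (ax$exprs[[i]]$kind != "named") next
        for (j in seq_along(ax$exprs)) {
          if (i == j || !expr_is_monotone_oracle(ax$exprs[[j]])) next
          crules[[length(crules) + 1L]] <-
            list(lhs = ax$exprs[[j]], rhs = ax$exprs[[i]]$id)
        }
      }
    }
    if (ax$type == "prop_assertion") {
      m$rel_ext[[ax$rel]] <- rbind(opairs(m, ax$rel), c(ax$from, ax$to))
    }
    if (ax$type == "class_assertion" && ax$expr$kind == "named") {
      m$class_ext[[ax$expr$id]] <- unique(c(oclass(m, ax$expr$id),
                                            ax$individual))
    }
  }
  if (!is.null(tax)) {
    for (sp in tax$specs) {
      if ("SYMMETRIC" %in% sp$flags) sym <- c(sym, sp$name)
      if ("TRANSITIVE" %in% sp$flags) trans <- c(trans, sp$name)
      if (!is.null(sp$parent)) {
        subp[[length(subp) + 1L]] <- c(sp$name, sp$parent)
      }
      if (!is.null(sp$inverse_of) && sp$name < sp$inverse_of) {
        inv[[length(inv) + 1L]] <- c(sp$name, sp$inverse_of)
      }
    }
  }
  # key sets are kept alongside the pair matrices purely as an index for
  # membership queries; the iteration itself stays naive (full passes)
  K <- lapply(m$rel_ext, function(p) if (nrow(p)) okey(p[, 1L], p[, 2L])
              else character(0))
  changed <- FALSE
  has <- function(rel, x, y) okey(x, y) %in% K[[rel]]
  addp <- function(rel, x, y) {
    if (!has(rel, x, y)) {
      m$rel_ext[[rel]] <<- rbind(opairs(m, rel), c(x, y))
      K[[rel]] <<- c(K[[rel]], okey(x, y))
      changed <<- TRUE
    }
  }
  repeat {
    changed <- FALSE
    for (r in sym) {
      p <- opairs(m, r)
      for (i in seq_len(nrow(p))) addp(r, p[i, 2L], p[i, 1L])
    }
    for (iv in inv) {
      for (d in list(iv, rev(iv))) {
        p <- opairs(m, d[[1L]])
        for (i in seq_len(nrow(p))) addp(d[[2L]], p[i, 2L], p[i, 1L])
      }
    }
    for (sp in subp) {
      p <- opairs(m, sp[[1L]])
      for (i in seq_len(nrow(p))) addp(sp[[2L]], p[i, 1L], p[i, 2L])
    }
    for (r in trans) {
      if (is.null(m$rel_ext[[r]])) next
      for (x in m$individuals) for (y in m$individuals) {
        if (!has(r, x, y)) next
        for (z in m$individuals) {
          if (has(r, y, z)) addp(r, x, z)
        }
      }
    }
    for (ch in chains) {
      if (length(ch$chain) != 2L) next
      if (is.null(m$rel_ext[[ch$chain[[1L]]]]) ||
          is.null(m$rel_ext[[ch$chain[[2L]]]])) next
      for (x in m$individuals) for (y in m$individuals) {
        if (!has(ch$chain[[1L]], x, y)) next
        for (z in m$individuals) {
          if (has(ch$chain[[2L]], y, z)) addp(ch$sup, x, z)
        }
      }
    }
    for (cr in crules) {
      for (x in fol_eval(cr$lhs, m)) {
        if (!(x %in% oclass(m, cr$rhs))) {
          m$class_ext[[cr$rhs]] <- c(oclass(m, cr$rhs), x)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  m
}

expr_is_monotone_oracle <- function(e) {
  if (is.character(e)) return(TRUE)
  if (e$kind == "not") return(FALSE)
  if (e$kind %in% c("and", "or")) {
    return(all(vapply(e$args, expr_is_monotone_oracle, TRUE)))
  }
  if (e$kind == "some") return(expr_is_monotone_oracle(e$filler))
  TRUE
}

# Direct FOL evaluation of every flag / disjointness / GCI / pattern
# contract on an (already closed) model; returns the set of violated
# categories, in the same category vocabulary as check().
fol_categories <- function(m, axioms, tax = NULL) {
  bad <- character(0)
  hit <- function(cat) bad <<- unique(c(bad, cat))
  # membership index over the fixed model under test
  KK <- lapply(m$rel_ext, function(p) if (nrow(p)) okey(p[, 1L], p[, 2L])
               else character(0))
  oholds <- function(m_unused, rel, x, y) okey(x, y) %in% KK[[rel]]
  flags <- list()
  for (ax in axioms) {
    if (ax$type == "characteristic") {
      flags[[length(flags) + 1L]] <- c(ax$rel, ax$which)
    }
  }
  if (!is.null(tax)) {
    for (r in names(m$rel_ext)) {
      sp <- tax$specs[[r]]
      if (!is.null(sp)) {
        for (fl in sp$flags) flags[[length(flags) + 1L]] <- c(r, fl)
      }
    }
  }
  flags <- unique(flags)
  for (f in flags) {
    r <- f[[1L]]; which <- f[[2L]]
    p <- opairs(m, r)
    field <- unique(as.vector(p))
    if (which == "REFLEXIVE") {
      for (x in field) if (!oholds(m, r, x, x)) hit("reflexivity")
    } else if (which == "IRREFLEXIVE") {
      for (x in field) if (oholds(m, r, x, x)) hit("irreflexivity")
    } else if (which == "SYMMETRIC") {
      for (i in seq_len(nrow(p))) {
        if (!oholds(m, r, p[i, 2L], p[i, 1L])) hit("symmetry")
      }
    } else if (which == "ASYMMETRIC") {
      for (i in seq_len(nrow(p))) {
        if (oholds(m, r, p[i, 2L], p[i, 1L])) hit("asymmetry")
      }
    } else if (which == "ANTISYMMETRIC") {
      for (i in seq_len(nrow(p))) {
        if (p[i, 1L] != p[i, 2L] && oholds(m, r, p[i, 2L], p[i, 1L])) {
          hit("antisymmetry")
        }
      }
    } else if (which == "STRONG_SUPPLEMENTATION") {
      overlaps <- function(z, x) {
        any(vapply(m$individuals, function(w)
          oholds(m, r, w, z) && oholds(m, r, w, x), TRUE))
      }
      for (y in field) {
        parts_y <- field[vapply(field, function(z) oholds(m, r, z, y), TRUE)]
        if (length(parts_y) == 0L) next
        for (x in field) {
          if (oholds(m, r, y, x)) next
          if (all(vapply(parts_y, overlaps, TRUE, x = x))) {
            hit("strong-supplementation")
          }
        }
      }
    }
  }
  for (ax in axioms) {
    if (ax$type == "subclass") {
      sub <- fol_eval(ax$sub, m); sup <- fol_eval(ax$sup, m)
      if (any(!(sub %in% sup))) hit("subclass")
    } else if (ax$type == "equivalent") {
      exts <- lapply(ax$exprs, fol_eval, m = m)
      for (i in seq_along(exts)[-1L]) {
        if (!setequal(exts[[1L]], exts[[i]])) hit("equivalence")
      }
    } else if (ax$type == "disjoint") {
      exts <- lapply(ax$exprs, fol_eval, m = m)
      for (i in seq_along(exts)) for (j in seq_along(exts)) {
        if (j > i && length(intersect(exts[[i]], exts[[j]]))) {
          hit("disjointness")
        }
      }
    } else if (ax$type == "class_assertion") {
      if (!(ax$individual %in% fol_eval(ax$expr, m))) hit("class-assertion")
    } else if (ax$type == "pattern" &&
               ax$pattern$name == "subclass-disjunction") {
      p <- ax$pattern
      sat_any <- FALSE
      for (k in p$kinds) {
        members <- intersect(oclass(m, p$ggp), oclass(m, k))
        ok <- TRUE
        for (x in members) {
          succ <- any(vapply(oclass(m, p$target), function(y)
            oholds(m, p$primitive, x, y), TRUE))
          if (!succ) { ok <- FALSE; break }
        }
        if (ok) { sat_any <- TRUE; break }
      }
      if (!sat_any) hit("pattern-subclass-disjunction")
    } else if (ax$type == "pattern" && ax$pattern$name == "proper-part-def") {
      pp <- opairs(m, ax$pattern$rel)
      for (i in seq_len(nrow(pp))) {
        x <- pp[i, 1L]; y <- pp[i, 2L]
        if (!oholds(m, ax$pattern$base, x, y) ||
            oholds(m, ax$pattern$base, y, x)) {
          hit("proper-part")
        }
      }
    }
  }
  sort(bad)
}

# All 16 binary relations on a 2-element domain; TRUE iff some NONEMPTY one
# satisfies every (semantic) flag in `flags`.
brute_flags_nonempty_satisfiable <- function(flags) {
  dom <- c("a", "b")
  cells <- expand.grid(x = dom, y = dom, stringsAsFactors = FALSE)
  for (code in 1:15) {  # skip 0 = empty relation
    sel <- bitwAnd(code %/% 2^(0:3), 1L) == 1L
    has <- function(x, y) any(sel & cells$x == x & cells$y == y)
    ok <- TRUE
    if ("REFLEXIVE" %in% flags) {
      ok <- ok && all(vapply(dom, function(x) has(x, x), TRUE))
    }
    if ("IRREFLEXIVE" %in% flags) {
      ok <- ok && !any(vapply(dom, function(x) has(x, x), TRUE))
    }
    for (x in dom) for (y in dom) {
      if ("SYMMETRIC" %in% flags && has(x, y) && !has(y, x)) ok <- FALSE
      if ("ASYMMETRIC" %in% flags && has(x, y) && has(y, x)) ok <- FALSE
      if ("ANTISYMMETRIC" %in% flags && x != y && has(x, y) && has(y, x)) {
        ok <- FALSE
      }
      if ("TRANSITIVE" %in% flags) {
        for (z in dom) if (has(x, y) && has(y, z) && !has(x, z)) ok <- FALSE
      }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# Random reflexive-transitive-antisymmetric relation (a partial order) on
# inds, built by reflexive-transitive-closing a random DAG edge set.
random_partial_order <- function(inds, p = 0.4) {
  n <- length(inds)
  pairs <- matrix(character(0), ncol = 2L)
  for (i in seq_len(n)) {
    pairs <- rbind(pairs, c(inds[i], inds[i]))
    for (j in seq_len(n)) {
      if (i < j && stats::runif(1) < p) {
        pairs <- rbind(pairs, c(inds[i], inds[j]))  # edges respect order: DAG
      }
    }
  }
  # transitive closure
  repeat {
    added <- FALSE
    keys <- okey(pairs[, 1L], pairs[, 2L])
    for (i in seq_len(nrow(pairs))) for (j in seq_len(nrow(pairs))) {
      if (pairs[i, 2L] == pairs[j, 1L]) {
        k <- okey(pairs[i, 1L], pairs[j, 2L])
        if (!(k %in% keys)) {
          pairs <- rbind(pairs, c(pairs[i, 1L], pairs[j, 2L]))
          keys <- c(keys, k)
          added <- TRUE
        }
      }
    }
    if (!added) break
  }
  pairs
}

# A compact axiom set over an abstract signature, exercising every closure
# rule and check category, for the small-scope oracle tests.
small_scope_axioms <- function() {
  enc <- ax_subclass(
    ce_some("owl:topObjectProperty",
            ce_and(ce_named("C1"), ce_named("C2"),
                   ce_not(ce_some("r1", ce_named("C2"))))),
    ce_nothing())
  list(
    ax_characteristic("r1", "TRANSITIVE"),
    ax_characteristic("r1", "ANTISYMMETRIC"),
    ax_characteristic("r1", "REFLEXIVE"),
    ax_characteristic("r2", "SYMMETRIC"),
    ax_characteristic("r2", "IRREFLEXIVE"),
    ax_characteristic("r2", "ASYMMETRIC"),
    ax_characteristic("r1", "STRONG_SUPPLEMENTATION"),
    ax_subprop("r2", "r1"),
    ax_chain(c("r1", "r2"), "r2"),
    ax_subclass("C1", "C2"),
    ax_disjoint("C1", "C2"),
    ax_subclass(ce_some("r2", "C1"), ce_named("C2")),
    ax_pattern("subclass-disjunction", ggp = "C1", relation = "R",
               primitive = "r1", target = "C2", kinds = c("C1", "C2"),
               encoded = enc)
  )
}

# Axiom set over the real taxonomy vocabulary for the random-model tests.
genia_scope_axioms <- function(tax = genia_taxonomy()) {
  c(background_axioms(tax),
    expand_subclass_pattern(
      pattern_instance("G_X", "GGP-subclass-has-part", "X"), tax),
    expand_variant_pattern(
      pattern_instance("G_X", "GGP-has-mutant", "X"), tax),
    define_ggp_class(
      ggp_class("G_X",
                tibble::tibble(class_id = "Xg", term_class = "DNA"),
                seed_dna_class = "Xg"), tax))
}
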