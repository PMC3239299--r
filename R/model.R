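#' Construct a finite model
#'
#' A finite interpretation for the axiom IR: a finite set of individuals,
#' class extensions (subsets of the individuals) and relation extensions
#' (sets of ordered pairs). This is the structure the closed-world model
#' checker closes and verifies.
#'
#' @param individuals character vector of individual names.
#' @param class_ext named list; each entry a character vector of members.
#' @param rel_ext named list; each entry a two-column matrix (or data frame,
#'   or list of length-2 vectors) of ordered pairs.
#' @return An object of class `ggprel_model`.
#' @examples
#' m <- finite_model(c("a", "b"),
#'                   class_ext = list(DNA = "a"),
#'                   rel_ext = list("II-part-of" = list(c("a", "b"))))
#' @export
finite_model <- function(individuals, class_ext = list(), rel_ext = list()) {
  individuals <- as.character(individuals)
  stopifnot(!anyDuplicated(individuals))
  class_ext <- lapply(class_ext, function(x) unique(as.character(x)))
  rel_ext <- lapply(rel_ext, as_pairs)
  for (nm in names(class_ext)) {
    bad <- setdiff(class_ext[[nm]], individuals)
    if (length(bad)) stop("class ", nm, ": unknown individual ", bad[1L])
  }
  for (nm in names(rel_ext)) {
    bad <- setdiff(as.vector(rel_ext[[nm]]), individuals)
    if (length(bad)) stop("relation ", nm, ": unknown individual ", bad[1L])
  }
  structure(list(individuals = individuals, class_ext = class_ext,
                 rel_ext = rel_ext),
            class = "ggprel_model")
}

as_pairs <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 2L)
    m <- matrix(as.character(x), ncol = 2L)
  } else if (is.data.frame(x)) {
    stopifnot(ncol(x) == 2L)
    m <- cbind(as.character(x[[1L]]), as.character(x[[2L]]))
  } else if (is.list(x)) {
    stopifnot(all(lengths(x) == 2L))
    m <- do.call(rbind, lapply(x, as.character))
    if (is.null(m)) m <- matrix(character(0), ncol = 2L)
  } else if (is.null(x) || length(x) == 0L) {
    m <- matrix(character(0), ncol = 2L)
  } else {
    stop("cannot interpret relation extension")
  }
  m[!duplicated(pair_keys(m)), , drop = FALSE]
}

SEP <- "\x1f"
pair_keys <- function(m) {
  if (nrow(m) == 0L) character(0) else paste(m[, 1L], m[, 2L], sep = SEP)
}

#' @export
print.ggprel_model <- function(x, ...) {
  cat("<finite model> ", length(x$individuals), " individuals, ",
      length(x$class_ext), " classes, ", length(x$rel_ext), " relations\n",
      sep = "")
  invisible(x)
}

model_pairs <- function(m, rel) {
  p <- m$rel_ext[[rel]]
  if (is.null(p)) matrix(character(0), ncol = 2L) else p
}

model_class <- function(m, id) {
  e <- m$class_ext[[id]]
  if (is.null(e)) character(0) else e
}

# Equality up to ordering of extensions.
model_equal <- function(a, b) {
  if (!setequal(a$individuals, b$individuals)) return(FALSE)
  cls <- union(names(a$class_ext), names(b$class_ext))
  for (k in cls) if (!setequal(model_class(a, k), model_class(b, k))) {
    return(FALSE)
  }
  rels <- union(names(a$rel_ext), names(b$rel_ext))
  for (k in rels) if (!setequal(pair_keys(model_pairs(a, k)),
                                pair_keys(model_pairs(b, k)))) {
    return(FALSE)
  }
  TRUE
}

# TRUE iff every extension of a is contained in the corresponding one of b.
model_subset <- function(a, b) {
  for (k in names(a$class_ext)) {
    if (!all(model_class(a, k) %in% model_class(b, k))) return(FALSE)
  }
  for (k in names(a$rel_ext)) {
    if (!all(pair_keys(model_pairs(a, k)) %in%
               pair_keys(model_pairs(b, k)))) {
      return(FALSE)
    }
  }
  TRUE
}

#' Evaluate a class expression on a finite model
#'
#' Closed-world evaluation: complements are taken relative to the model's
#' individuals, and `owl:topObjectProperty` denotes the universal relation.
#'
#' @param e a class expression ([ce_named()] and friends) or identifier.
#' @param m a [finite_model()].
#' @return Character vector of individuals in the extension.
#' @export
eval_expr <- function(e, m) {
  e <- as_expr(e)
  switch(e$kind,
    named   = model_class(m, e$id),
    thing   = m$individuals,
    nothing = character(0),
    not     = setdiff(m$individuals, eval_expr(e$arg, m)),
    and     = Reduce(intersect, lapply(e$args, eval_expr, m = m)),
    or      = Reduce(union, lapply(e$args, eval_expr, m = m)),
    some    = {
      filler <- eval_expr(e$filler, m)
      if (e$rel == "owl:topObjectProperty") {
        if (length(filler)) m$individuals else character(0)
      } else {
        p <- model_pairs(m, e$rel)
        unique(p[p[, 2L] %in% filler, 1L])
      }
    })
}

# ---- closure ----------------------------------------------------------------

# Extract closure-relevant rules from an axiom list (optionally augmented
# with a taxonomy's flags / parent / inverse links).
closure_rules <- function(axioms, taxonomy = NULL) {
  sym <- character(0); trans <- character(0)
  subprop <- list(); chains <- list(); inv <- list()
  class_rules <- list(); cls_seed <- list(); pair_seed <- list()
  for (ax in axioms) {
    switch(ax$type,
      characteristic = {
        if (ax$which == "SYMMETRIC") sym <- c(sym, ax$rel)
        if (ax$which == "TRANSITIVE") trans <- c(trans, ax$rel)
      },
      subprop = { subprop[[length(subprop) + 1L]] <- c(ax$sub, ax$sup) },
      chain = { chains[[length(chains) + 1L]] <- ax },
      inverse = { inv[[length(inv) + 1L]] <- c(ax$rel1, ax$rel2) },
      subclass = {
        if (ax$sup$kind == "named" && expr_monotone(ax$sub)) {
          class_rules[[length(class_rules) + 1L]] <-
            list(lhs = ax$sub, rhs = ax$sup$id)
        }
      },
      equivalent = {
        for (i in seq_along(ax$exprs)) {
          tgt <- ax$exprs[[i]]
          if (tgt$kind != "named") next
          for (j in seq_along(ax$exprs)) {
            if (i == j || !expr_monotone(ax$exprs[[j]])) next
            class_rules[[length(class_rules) + 1L]] <-
              list(lhs = ax$exprs[[j]], rhs = tgt$id)
          }
        }
      },
      class_assertion = {
        if (ax$expr$kind == "named") {
          cls_seed[[length(cls_seed) + 1L]] <- c(ax$expr$id, ax$individual)
        }
      },
      prop_assertion = {
        pair_seed[[length(pair_seed) + 1L]] <- c(ax$rel, ax$from, ax$to)
      },
      NULL)
  }
  if (!is.null(taxonomy)) {
    for (sp in taxonomy$specs) {
      if ("SYMMETRIC" %in% sp$flags) sym <- c(sym, sp$name)
      if ("TRANSITIVE" %in% sp$flags) trans <- c(trans, sp$name)
      if (!is.null(sp$parent)) {
        subprop[[length(subprop) + 1L]] <- c(sp$name, sp$parent)
      }
      if (!is.null(sp$inverse_of) && sp$name < sp$inverse_of) {
        inv[[length(inv) + 1L]] <- c(sp$name, sp$inverse_of)
      }
    }
  }
  list(sym = unique(sym), trans = unique(trans), subprop = subprop,
       chains = chains, inv = inv, class_rules = class_rules,
       cls_seed = cls_seed, pair_seed = pair_seed)
}

#' Deductive closure of a finite model
#'
#' Computes the least fixpoint of the model under the axioms' monotone
#' rules: symmetry and transitivity of flagged relations, sub-property
#' propagation, property-chain firing, inverse-property synchronisation,
#' asserted facts, and class-extension propagation along `SubClassOf` /
#' `EquivalentClasses` axioms whose firing side is monotone (no complement)
#' and whose receiving side is a named class. Only additions are ever made.
#' Transitive closure runs delta-based (new pairs only are re-joined); the
#' remaining rules run as change-flagged passes.
#'
#' When a taxonomy is supplied, its flags, parent links and inverse links
#' are added to the rules extracted from the axioms.
#'
#' @param m a [finite_model()].
#' @param axioms list of axioms.
#' @param taxonomy optional `ggprel_taxonomy`.
#' @return The closed [finite_model()], with attribute `"derivations"`: a
#'   named list (key `rel<US>x<US>y`) recording each derived pair's rule and
#'   premise keys, for witness-chain reporting.
#' @export
closure <- function(m, axioms, taxonomy = NULL) {
  stopifnot(inherits(m, "ggprel_model"))
  rules <- closure_rules(axioms, taxonomy)
  inds <- m$individuals
  rel <- m$rel_ext
  cls <- m$class_ext
  deriv <- list()
  keys <- lapply(rel, pair_keys)

  has_pair <- function(r, key) {
    !is.null(keys[[r]]) && key %in% keys[[r]]
  }
  add_pair <- function(r, x, y, rule = NULL, premises = NULL) {
    key <- paste(x, y, sep = SEP)
    if (has_pair(r, key)) return(FALSE)
    if (is.null(rel[[r]])) rel[[r]] <<- matrix(character(0), ncol = 2L)
    rel[[r]] <<- rbind(rel[[r]], c(x, y))
    keys[[r]] <<- c(keys[[r]], key)
    if (!is.null(rule)) {
      deriv[[paste(r, key, sep = SEP)]] <<- list(rel = r, x = x, y = y,
                                                 rule = rule,
                                                 premises = premises)
    }
    TRUE
  }
  add_member <- function(k, x, rule = NULL) {
    if (x %in% cls[[k]]) return(FALSE)
    cls[[k]] <<- c(cls[[k]], x)
    TRUE
  }
  snapshot <- function() {
    structure(list(individuals = inds, class_ext = cls, rel_ext = rel),
              class = "ggprel_model")
  }

  # Seed asserted facts.
  for (s in rules$cls_seed) {
    if (!s[[2L]] %in% inds) stop("asserted individual ", s[[2L]],
                                 " not in model")
    add_member(s[[1L]], s[[2L]])
  }
  for (s in rules$pair_seed) {
    if (!all(s[2:3] %in% inds)) stop("asserted individuals not in model")
    add_pair(s[[1L]], s[[2L]], s[[3L]], rule = "assertion")
  }

  pk <- function(r, x, y) paste(r, x, y, sep = SEP)
  repeat {
    changed <- FALSE
    for (iv in rules$inv) {
      for (d in list(iv, rev(iv))) {
        p <- rel[[d[[1L]]]]
        if (is.null(p)) next
        for (i in seq_len(nrow(p))) {
          if (add_pair(d[[2L]], p[i, 2L], p[i, 1L], rule = "inverse",
                       premises = pk(d[[1L]], p[i, 1L], p[i, 2L]))) {
            changed <- TRUE
          }
        }
      }
    }
    for (r in rules$sym) {
      p <- rel[[r]]
      if (is.null(p)) next
      for (i in seq_len(nrow(p))) {
        if (add_pair(r, p[i, 2L], p[i, 1L], rule = "symmetry",
                     premises = pk(r, p[i, 1L], p[i, 2L]))) {
          changed <- TRUE
        }
      }
    }
    for (sp in rules$subprop) {
      p <- rel[[sp[[1L]]]]
      if (is.null(p)) next
      for (i in seq_len(nrow(p))) {
        if (add_pair(sp[[2L]], p[i, 1L], p[i, 2L], rule = "subproperty",
                     premises = pk(sp[[1L]], p[i, 1L], p[i, 2L]))) {
          changed <- TRUE
        }
      }
    }
    # Transitivity: delta-based -- only newly added pairs are re-joined.
    for (r in rules$trans) {
      if (is.null(rel[[r]]) || nrow(rel[[r]]) == 0L) next
      delta <- rel[[r]]
      while (nrow(delta) > 0L) {
        new <- matrix(character(0), ncol = 2L)
        all_p <- rel[[r]]
        for (i in seq_len(nrow(delta))) {
          x <- delta[i, 1L]; y <- delta[i, 2L]
          # (x,y) o (y,z) and (w,x) o (x,y)
          zs <- all_p[all_p[, 1L] == y, 2L]
          for (z in zs) {
            if (add_pair(r, x, z, rule = "transitivity",
                         premises = c(pk(r, x, y), pk(r, y, z)))) {
              new <- rbind(new, c(x, z)); changed <- TRUE
            }
          }
          ws <- all_p[all_p[, 2L] == x, 1L]
          for (w in ws) {
            if (add_pair(r, w, y, rule = "transitivity",
                         premises = c(pk(r, w, x), pk(r, x, y)))) {
              new <- rbind(new, c(w, y)); changed <- TRUE
            }
          }
        }
        delta <- new
      }
    }
    for (ch in rules$chains) {
      # Binary chains (the shipped axioms use length 2); longer chains fold.
      comp <- rel[[ch$chain[[1L]]]]
      prem_of <- NULL
      if (!is.null(comp) && nrow(comp) > 0L) {
        prem_of <- lapply(seq_len(nrow(comp)), function(i)
          pk(ch$chain[[1L]], comp[i, 1L], comp[i, 2L]))
      }
      for (j in seq_along(ch$chain)[-1L]) {
        nxt <- rel[[ch$chain[[j]]]]
        if (is.null(comp) || is.null(nxt) || nrow(comp) == 0L ||
            nrow(nxt) == 0L) {
          comp <- matrix(character(0), ncol = 2L); prem_of <- list(); break
        }
        res <- matrix(character(0), ncol = 2L); prems <- list()
        for (i in seq_len(nrow(comp))) {
          hits <- which(nxt[, 1L] == comp[i, 2L])
          for (h in hits) {
            res <- rbind(res, c(comp[i, 1L], nxt[h, 2L]))
            prems[[length(prems) + 1L]] <-
              c(prem_of[[i]], pk(ch$chain[[j]], nxt[h, 1L], nxt[h, 2L]))
          }
        }
        comp <- res; prem_of <- prems
      }
      if (!is.null(comp) && nrow(comp) > 0L) {
        for (i in seq_len(nrow(comp))) {
          if (add_pair(ch$sup, comp[i, 1L], comp[i, 2L],
                       rule = "property-chain", premises = prem_of[[i]])) {
            changed <- TRUE
          }
        }
      }
    }
    for (cr in rules$class_rules) {
      ext <- eval_expr(cr$lhs, snapshot())
      for (x in ext) {
        if (add_member(cr$rhs, x)) changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- snapshot()
  attr(out, "derivations") <- deriv
  out
}

#' The defined extension of proper parthood
#'
#' Evaluates the proper-parthood definition on a model: all pairs `(x, y)`
#' with `x II-part-of y` and not `y II-part-of x`. On a reflexive,
#' transitive, antisymmetric parthood this equals parthood minus the
#' identity pairs.
#'
#' @param m a [finite_model()] (close it first if derived parthood pairs
#'   should count).
#' @param base the parthood relation identifier.
#' @return Two-column character matrix of pairs.
#' @export
proper_part_extension <- function(m, base = "II-part-of") {
  p <- model_pairs(m, base)
  if (nrow(p) == 0L) return(p)
  k <- pair_keys(p)
  rk <- paste(p[, 2L], p[, 1L], sep = SEP)
  p[!(rk %in% k), , drop = FALSE]
}

# Human-readable derivation chain for a pair, from closure()'s derivations.
explain_pair <- function(m, rel, x, y) {
  deriv <- attr(m, "derivations")
  fmt <- function(key) {
    parts <- strsplit(key, SEP, fixed = TRUE)[[1L]]
    lab <- paste0(parts[[1L]], "(", parts[[2L]], ", ", parts[[3L]], ")")
    d <- deriv[[key]]
    if (is.null(d)) return(lab)
    paste0(lab, " <= ", d$rule, "[",
           paste(vapply(d$premises, fmt, ""), collapse = "; "), "]")
  }
  fmt(paste(rel, x, y, sep = SEP))
}
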