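#' Check a finite model against axioms
#'
#' Closed-world verification: the model is first deductively closed (see
#' [closure()]), then every axiom and every relation characteristic is
#' evaluated on the closed model, producing a violation report with explicit
#' witnesses. An empty report means the model is consistent with the axioms.
#' This is deliberately stronger than open-world OWL entailment: an
#' unsatisfied existential obligation is reported as a violation instead of
#' being satisfied by an invented anonymous individual, because annotation
#' verification wants witnesses, not skolems.
#'
#' Characteristics checked (with witnesses): reflexivity (over the relation's
#' declared domain-class extension, or over the individuals occurring in the
#' relation when no domain is declared; `reflexivity = "global"` switches to
#' all individuals), irreflexivity, symmetry, asymmetry, antisymmetry, and
#' strong supplementation (if every part of `y` overlaps `x`, then `y` must
#' be a part of `x`). Pattern axioms (the kind-disjunction pattern and the
#' proper-parthood definition) are evaluated natively.
#'
#' @param m a [finite_model()].
#' @param axioms list of axioms.
#' @param taxonomy a `ggprel_taxonomy`; its flags are checked for every
#'   relation present in the model.
#' @param close close the model first (default `TRUE`; pass `FALSE` for an
#'   already-closed model).
#' @param reflexivity `"restricted"` (default) or `"global"`.
#' @return A tibble of class `ggprel_violations` with columns `category`,
#'   `subject`, `witness`, `message`, `derivation`.
#' @examples
#' m <- finite_model("g", rel_ext = list("II-has-mutant" = list(c("g", "g"))))
#' check(m, list())  # irreflexivity violation with witness g
#' @export
check <- function(m, axioms, taxonomy = genia_taxonomy(), close = TRUE,
                  reflexivity = c("restricted", "global")) {
  stopifnot(inherits(m, "ggprel_model"))
  reflexivity <- match.arg(reflexivity)
  if (close) m <- closure(m, axioms, taxonomy)
  v_cat <- character(0); v_sub <- character(0); v_wit <- character(0)
  v_msg <- character(0); v_der <- character(0)
  add <- function(category, subject, witness, message, derivation = NA_character_) {
    n <- length(v_cat) + 1L
    v_cat[n] <<- category; v_sub[n] <<- subject; v_wit[n] <<- witness
    v_msg[n] <<- message; v_der[n] <<- derivation
  }

  # --- relation characteristics ---------------------------------------------
  chars <- list()
  seen <- character(0)
  note <- function(rel, which) {
    key <- paste(rel, which)
    if (!key %in% seen) {
      seen <<- c(seen, key)
      chars[[length(chars) + 1L]] <<- c(rel, which)
    }
  }
  for (ax in axioms) {
    if (ax$type == "characteristic") note(ax$rel, ax$which)
  }
  if (!is.null(taxonomy)) {
    for (rel in names(m$rel_ext)) {
      sp <- taxonomy$specs[[rel]]
      if (!is.null(sp)) for (fl in sp$flags) note(rel, fl)
    }
  }
  for (cf in chars) {
    rel <- cf[[1L]]; which <- cf[[2L]]
    p <- model_pairs(m, rel)
    k <- pair_keys(p)
    field <- unique(as.vector(p))
    if (which == "REFLEXIVE") {
      dom <- if (reflexivity == "global") {
        m$individuals
      } else {
        sp <- if (!is.null(taxonomy)) taxonomy$specs[[rel]] else NULL
        if (!is.null(sp) && !is.null(sp$domain_class)) {
          model_class(m, sp$domain_class)
        } else {
          field
        }
      }
      for (x in dom) {
        if (!(paste(x, x, sep = SEP) %in% k)) {
          add("reflexivity", rel, x,
              paste0(rel, " is reflexive but (", x, ",", x, ") is missing"))
        }
      }
    } else if (which == "IRREFLEXIVE") {
      loops <- p[p[, 1L] == p[, 2L], 1L]
      for (x in loops) {
        add("irreflexivity", rel, x,
            paste0(rel, " is irreflexive but contains (", x, ",", x, ")"),
            explain_pair(m, rel, x, x))
      }
    } else if (which == "SYMMETRIC") {
      for (i in seq_len(nrow(p))) {
        if (!(paste(p[i, 2L], p[i, 1L], sep = SEP) %in% k)) {
          add("symmetry", rel, paste0(p[i, 1L], ",", p[i, 2L]),
              paste0(rel, " is symmetric but (", p[i, 2L], ",", p[i, 1L],
                     ") is missing"))
        }
      }
    } else if (which %in% c("ASYMMETRIC", "ANTISYMMETRIC")) {
      for (i in seq_len(nrow(p))) {
        x <- p[i, 1L]; y <- p[i, 2L]
        if (x > y || (x == y && which == "ANTISYMMETRIC")) next
        mutual <- paste(y, x, sep = SEP) %in% k
        if (which == "ASYMMETRIC" && mutual) {
          add("asymmetry", rel, paste0(x, ",", y),
              paste0(rel, " is asymmetric but holds in both directions for (",
                     x, ",", y, ")"),
              explain_pair(m, rel, y, x))
        }
        if (which == "ANTISYMMETRIC" && mutual && x != y) {
          add("antisymmetry", rel, paste0(x, ",", y),
              paste0(rel, " is antisymmetric but (", x, ",", y, ") and (",
                     y, ",", x, ") both hold for distinct individuals"))
        }
      }
    } else if (which == "STRONG_SUPPLEMENTATION") {
      parts_of <- function(y) p[p[, 2L] == y, 1L]
      overlaps <- function(z, x) {
        wz <- p[p[, 2L] == z, 1L]
        wx <- p[p[, 2L] == x, 1L]
        length(intersect(wz, wx)) > 0L
      }
      for (y in field) {
        py <- parts_of(y)
        if (length(py) == 0L) next
        for (x in field) {
          if (paste(y, x, sep = SEP) %in% k) next
          if (all(vapply(py, overlaps, TRUE, x = x))) {
            add("strong-supplementation", rel, paste0(x, ",", y),
                paste0("every ", rel, "-part of ", y, " overlaps ", x,
                       " but ", y, " is not ", rel, " ", x))
          }
        }
      }
    }
  }

  # --- class axioms and patterns --------------------------------------------
  for (ax in axioms) {
    if (ax$type == "subclass") {
      sub_ext <- eval_expr(ax$sub, m)
      sup_ext <- eval_expr(ax$sup, m)
      missing <- setdiff(sub_ext, sup_ext)
      for (w in missing) {
        add("subclass", axiom_str(ax), w,
            paste0(w, " is in ", expr_str(ax$sub), " but not in ",
                   expr_str(ax$sup)),
            witness_derivation(m, ax$sub, w))
      }
    } else if (ax$type == "equivalent") {
      exts <- lapply(ax$exprs, eval_expr, m = m)
      for (i in seq_along(exts)[-1L]) {
        diffs <- c(setdiff(exts[[1L]], exts[[i]]),
                   setdiff(exts[[i]], exts[[1L]]))
        for (w in diffs) {
          add("equivalence", axiom_str(ax), w,
              paste0(w, " distinguishes the declared-equivalent classes ",
                     expr_str(ax$exprs[[1L]]), " and ",
                     expr_str(ax$exprs[[i]])))
        }
      }
    } else if (ax$type == "disjoint") {
      exts <- lapply(ax$exprs, eval_expr, m = m)
      for (i in seq_along(exts)) {
        for (j in seq_along(exts)) {
          if (j <= i) next
          for (w in intersect(exts[[i]], exts[[j]])) {
            add("disjointness", axiom_str(ax), w,
                paste0(w, " is in both ", expr_str(ax$exprs[[i]]), " and ",
                       expr_str(ax$exprs[[j]])))
          }
        }
      }
    } else if (ax$type == "class_assertion") {
      if (!ax$individual %in% eval_expr(ax$expr, m)) {
        add("class-assertion", axiom_str(ax), ax$individual,
            paste0(ax$individual, " asserted in ", expr_str(ax$expr),
                   " but not derivable"))
      }
    } else if (ax$type == "pattern") {
      nmp <- ax$pattern$name
      if (nmp == "subclass-disjunction") {
        res <- eval_subclass_disjunction(m, ax$pattern)
        if (!res$satisfied) {
          add("pattern-subclass-disjunction",
              paste0(ax$pattern$relation, "(", ax$pattern$ggp, ", ",
                     ax$pattern$target, ")"),
              "universal",
              paste0("no kind subclass of ", ax$pattern$ggp,
                     " satisfies the disjunction: ",
                     paste(res$reasons, collapse = "; ")))
        }
      } else if (nmp == "proper-part-def") {
        pp <- model_pairs(m, ax$pattern$rel)
        base_k <- pair_keys(model_pairs(m, ax$pattern$base))
        for (i in seq_len(nrow(pp))) {
          x <- pp[i, 1L]; y <- pp[i, 2L]
          if (!(paste(x, y, sep = SEP) %in% base_k)) {
            add("proper-part", ax$pattern$rel, paste0(x, ",", y),
                paste0(x, " is a proper part of ", y, " but not a ",
                       ax$pattern$base, " of it"))
          } else if (paste(y, x, sep = SEP) %in% base_k) {
            add("proper-part", ax$pattern$rel, paste0(x, ",", y),
                paste0(x, " proper part of ", y, " but parthood is mutual (",
                       "proper parthood excludes coincidence)"))
          }
        }
      }
    }
  }
  report <- tibble::tibble(category = v_cat, subject = v_sub,
                           witness = v_wit, message = v_msg,
                           derivation = v_der)
  class(report) <- c("ggprel_violations", class(report))
  attr(report, "model") <- m
  report
}

# Native evaluation of the kind-disjunction pattern.
eval_subclass_disjunction <- function(m, p) {
  g <- model_class(m, p$ggp)
  target <- model_class(m, p$target)
  reasons <- character(0)
  for (k in p$kinds) {
    members <- intersect(g, model_class(m, k))
    rp <- model_pairs(m, p$primitive)
    ok <- vapply(members, function(x)
      any(rp[, 1L] == x & rp[, 2L] %in% target), TRUE)
    if (all(ok)) {
      return(list(satisfied = TRUE, kind = k, reasons = character(0)))
    }
    cex <- members[!ok][1L]
    reasons <- c(reasons, paste0(k, " fails at ", cex))
  }
  list(satisfied = FALSE, kind = NA_character_, reasons = reasons)
}

# Derivation chains for a witness of a violated GCI: explain the relation
# pairs through which the witness satisfies the axiom's left-hand side.
witness_derivation <- function(m, expr, x) {
  chains <- collect_derivations(m, expr, x)
  if (length(chains) == 0L) return(NA_character_)
  paste(unique(chains), collapse = " AND ")
}

collect_derivations <- function(m, e, x) {
  switch(e$kind,
    and = unlist(lapply(e$args, collect_derivations, m = m, x = x)),
    or  = unlist(lapply(e$args, collect_derivations, m = m, x = x)),
    some = {
      filler <- eval_expr(e$filler, m)
      if (e$rel == "owl:topObjectProperty") {
        unlist(lapply(filler, function(y)
          collect_derivations(m, e$filler, y)))
      } else {
        p <- model_pairs(m, e$rel)
        ys <- p[p[, 1L] == x & p[, 2L] %in% filler, 2L]
        if (length(ys) == 0L) return(character(0))
        y <- ys[[1L]]
        c(explain_pair(m, e$rel, x, y),
          collect_derivations(m, e$filler, y))
      }
    },
    character(0))
}

#' @export
print.ggprel_violations <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("No violations: model is consistent with the axioms.\n")
  } else {
    cat(nrow(x), "violation(s):\n")
    for (i in seq_len(nrow(x))) {
      cat(" -", x$category[i], "|", x$subject[i], "| witness:",
          x$witness[i], "\n   ", x$message[i], "\n")
      if (!is.na(x$derivation[i])) cat("    via:", x$derivation[i], "\n")
    }
  }
  invisible(x)
}

#' Tidy a violation report
#'
#' @param x a `ggprel_violations` report.
#' @param ... unused.
#' @return A plain tibble (drops the report class and attributes).
#' @export
tidy.ggprel_violations <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ggprel_violations")
  attr(out, "model") <- NULL
  tibble::as_tibble(out)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")
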