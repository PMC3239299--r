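#' Construct a canonical model for a converted document
#'
#' Builds a finite model that realizes a document's axioms under the
#' closed-world reading: one individual is seeded per mention-denoted class,
#' existential obligations (`SubClassOf` with an existential right-hand
#' side) are repaired by linking to an existing member of the filler when
#' one exists and by creating a fresh individual otherwise, the GGP class
#' equivalence is repaired along the transcription/translation chain
#' according to the member's kind, and reflexivity self-loops are added for
#' reflexive relations in play. The chase is bounded by `max_new` fresh
#' individuals.
#'
#' The preference for existing filler members is deliberate: it keeps the
#' model minimal (desk-scale annotation verification), at the price of
#' reporting closed-world violations a more generous open-world model could
#' avoid. [check()] on the result reveals the inconsistencies a document's
#' axioms force on its own mentions.
#'
#' @param axioms list of axioms (e.g. from [convert_abstract()]).
#' @param seed_classes classes to seed with one individual each; defaults to
#'   every class `C` declared with an axiom `SubClassOf(C, <term class>)`
#'   pattern, i.e. the mention-denoted classes.
#' @param tax the relation taxonomy.
#' @param max_new bound on fresh individuals created by repairs.
#' @return A closed [finite_model()].
#' @export
canonical_model <- function(axioms, seed_classes = NULL,
                            tax = genia_taxonomy(), max_new = 50L) {
  if (is.null(seed_classes)) {
    term_classes <- c("DNA", "RNA", "Protein", "GGP")
    sups <- unique(unlist(lapply(axioms, function(ax) {
      if (ax$type == "subclass" && ax$sup$kind == "named") ax$sup$id
    })))
    # mention classes: named subclasses of something, that are not
    # themselves kind/term classes or GGP classes
    cand <- unique(unlist(lapply(axioms, function(ax) {
      if (ax$type == "subclass" && ax$sub$kind == "named" &&
          ax$sup$kind == "named") {
        ax$sub$id
      }
    })))
    seed_classes <- setdiff(cand, c(term_classes, sups[startsWith(sups, "G_")]))
    seed_classes <- seed_classes[!startsWith(seed_classes, "G_")]
  }
  seed_classes <- sort(unique(seed_classes))
  inds <- paste0("x_", seed_classes)
  cls <- stats::setNames(as.list(inds), seed_classes)
  m <- finite_model(inds, class_ext = cls)
  fresh_n <- 0L
  fresh <- function() {
    fresh_n <<- fresh_n + 1L
    paste0("y", fresh_n)
  }
  add_ind <- function(m, x) {
    m$individuals <- c(m$individuals, x)
    m
  }
  put_class <- function(m, id, x) {
    m$class_ext[[id]] <- unique(c(model_class(m, id), x))
    m
  }
  put_pair <- function(m, rel, x, y) {
    m$rel_ext[[rel]] <- as_pairs(rbind(model_pairs(m, rel), c(x, y)))
    m
  }
  # assert x into the named components of a (named / intersection-of-named)
  # filler; returns NULL if the filler is outside the repairable shapes
  assert_into <- function(m, e, x) {
    if (e$kind == "named") return(put_class(m, e$id, x))
    if (e$kind == "and") {
      for (a in e$args) {
        if (a$kind != "named") return(NULL)
      }
      for (a in e$args) m <- put_class(m, a$id, x)
      return(m)
    }
    NULL
  }

  repeat {
    m <- pad_reflexive(m)
    m <- closure(m, axioms, tax)
    m$individuals <- unique(m$individuals)
    repaired <- FALSE
    for (ax in axioms) {
      if (ax$type == "subclass" && ax$sup$kind == "some" &&
          ax$sup$rel != "owl:topObjectProperty") {
        need <- setdiff(eval_expr(ax$sub, m), eval_expr(ax$sup, m))
        for (x in need) {
          if (fresh_n >= max_new) break
          filler <- eval_expr(ax$sup$filler, m)
          if (length(filler)) {
            m <- put_pair(m, ax$sup$rel, x, filler[[1L]])
            repaired <- TRUE
          } else {
            y <- fresh()
            m2 <- assert_into(add_ind(m, y), ax$sup$filler, y)
            if (is.null(m2)) { fresh_n <- fresh_n - 1L; next }
            m <- put_pair(m2, ax$sup$rel, x, y)
            repaired <- TRUE
          }
        }
      } else if (ax$type == "equivalent" && length(ax$exprs) == 2L) {
        # GGP definition: G equivalent to C or some(tf, C) or
        # some(tl, some(tf, C)) -- repair a member along its kind's chain.
        g <- ax$exprs[[1L]]
        u <- ax$exprs[[2L]]
        if (g$kind != "named" || u$kind != "or" || length(u$args) != 3L) next
        seed <- u$args[[1L]]
        if (seed$kind != "named") next
        need <- setdiff(eval_expr(g, m), eval_expr(u, m))
        for (x in need) {
          if (fresh_n >= max_new) break
          sc <- model_class(m, seed$id)
          if (length(sc) == 0L) {
            m <- put_class(m, seed$id, x)
            repaired <- TRUE
            next
          }
          if (x %in% model_class(m, "RNA")) {
            m <- put_pair(m, "transcribed-from", x, sc[[1L]])
          } else if (x %in% model_class(m, "Protein")) {
            rna <- intersect(
              model_class(m, "RNA"),
              model_pairs(m, "transcribed-from")[, 1L])
            if (length(rna) == 0L) {
              y <- fresh()
              m <- put_class(add_ind(m, y), "RNA", y)
              m <- put_pair(m, "transcribed-from", y, sc[[1L]])
              rna <- y
            }
            m <- put_pair(m, "translated-from", x, rna[[1L]])
          } else {
            m <- put_class(m, seed$id, x)
          }
          repaired <- TRUE
        }
      }
    }
    if (!repaired) break
  }
  m
}
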