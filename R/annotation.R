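#' Construct an abstract annotation
#'
#' A validated in-memory representation of one standoff-annotated abstract:
#' the text, term mentions typed with term-ontology classes, binary relation
#' mentions between term mentions, and equivalence links grouping mentions
#' that denote a single gene/gene-product (GGP).
#'
#' Offsets are 0-based, half-open, counted in Unicode code points.
#'
#' @param doc_id document identifier.
#' @param text abstract text.
#' @param terms data frame with columns `id`, `term_class`, `start`, `end`,
#'   `surface`.
#' @param relations data frame with columns `id`, `label`, `arg1`, `arg2`.
#' @param equivs list of character vectors of term ids (merged transitively
#'   and normalized to disjoint groups).
#' @return An object of class `ggprel_annotation`.
#' @export
abstract_annotation <- function(doc_id, text, terms = NULL, relations = NULL,
                                equivs = list()) {
  empty_terms <- tibble::tibble(id = character(0), term_class = character(0),
                                start = integer(0), end = integer(0),
                                surface = character(0))
  empty_rels <- tibble::tibble(id = character(0), label = character(0),
                               arg1 = character(0), arg2 = character(0))
  terms <- if (is.null(terms) || nrow(terms) == 0L) empty_terms else
    tibble::as_tibble(terms)
  relations <- if (is.null(relations) || nrow(relations) == 0L) empty_rels else
    tibble::as_tibble(relations)
  a <- structure(list(doc_id = doc_id, text = text, terms = terms,
                      relations = relations,
                      equivs = normalize_equivs(equivs)),
                 class = "ggprel_annotation")
  validate_annotation(a)
  a
}

# Merge equivalence groups transitively; result is disjoint, each sorted by
# first-mention order is not needed -- keep insertion order of first member.
normalize_equivs <- function(equivs) {
  if (length(equivs) == 0L) return(list())
  groups <- list()
  for (g in equivs) {
    g <- as.character(g)
    hit <- which(vapply(groups, function(x) any(g %in% x), TRUE))
    if (length(hit) == 0L) {
      groups[[length(groups) + 1L]] <- unique(g)
    } else {
      merged <- unique(c(unlist(groups[hit]), g))
      groups <- groups[-hit]
      groups[[length(groups) + 1L]] <- merged
    }
  }
  groups
}

validate_annotation <- function(a) {
  t <- a$terms
  if (anyDuplicated(t$id)) {
    stop("duplicate term id: ", t$id[duplicated(t$id)][1L])
  }
  n <- nchar(a$text)
  for (i in seq_len(nrow(t))) {
    if (!(t$start[i] >= 0L && t$start[i] < t$end[i] && t$end[i] <= n)) {
      stop("term ", t$id[i], ": span [", t$start[i], ",", t$end[i],
           ") out of bounds for text of length ", n)
    }
    slice <- substr(a$text, t$start[i] + 1L, t$end[i])
    if (!identical(slice, t$surface[i])) {
      stop("term ", t$id[i], ": surface ", dQuote(t$surface[i]),
           " does not match text slice ", dQuote(slice))
    }
  }
  r <- a$relations
  if (nrow(r) > 0L) {
    if (anyDuplicated(r$id)) {
      stop("duplicate relation id: ", r$id[duplicated(r$id)][1L])
    }
    for (i in seq_len(nrow(r))) {
      for (arg in c(r$arg1[i], r$arg2[i])) {
        if (!arg %in% t$id) {
          stop("relation ", r$id[i], ": dangling argument reference ", arg)
        }
      }
      if (identical(r$arg1[i], r$arg2[i])) {
        stop("relation ", r$id[i], ": arg1 and arg2 are the same mention")
      }
    }
  }
  for (g in a$equivs) {
    if (length(g) < 2L) stop("equivalence group with fewer than 2 members")
    bad <- setdiff(g, t$id)
    if (length(bad)) stop("equivalence link references unknown term ", bad[1L])
  }
  invisible(a)
}

#' @export
print.ggprel_annotation <- function(x, ...) {
  cat("<annotation> ", x$doc_id, ": ", nrow(x$terms), " terms, ",
      nrow(x$relations), " relations, ", length(x$equivs),
      " equivalence groups\n", sep = "")
  invisible(x)
}

#' Parse a standoff annotation document
#'
#' Parses BioNLP-shared-task-style standoff annotation against its abstract
#' text. Term lines are `Tn<TAB><Class> <start> <end><TAB><surface>`, relation
#' lines `Rn<TAB><Label> Arg1:Tx Arg2:Ty`, equivalence lines
#' `*<TAB>Equiv Tx Ty [Tz ...]`. Offsets are 0-based half-open Unicode code
#' points; each term's surface is validated against the text slice.
#'
#' @param txt_document abstract text (single string; may contain newlines).
#' @param ann_document standoff annotation content (single string).
#' @param doc_id document identifier to record.
#' @return A validated [abstract_annotation()].
#' @examples
#' a <- parse_annotation("CD19 is expressed.", "T1\tProtein 0 4\tCD19")
#' a$terms
#' @export
parse_annotation <- function(txt_document, ann_document, doc_id = "doc") {
  stopifnot(is.character(txt_document), length(txt_document) == 1L,
            is.character(ann_document), length(ann_document) == 1L)
  lines <- strsplit(ann_document, "\n", fixed = TRUE)[[1]]
  terms <- list(); rels <- list(); equivs <- list()
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(line)) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    id <- fields[[1]]
    if (grepl("^T[0-9]+$", id)) {
      if (length(fields) != 3L) {
        stop("line ", ln, ": malformed term line (expected 3 tab fields)")
      }
      m <- regmatches(fields[[2]],
                      regexec("^(\\S+) ([0-9]+) ([0-9]+)$", fields[[2]]))[[1]]
      if (length(m) != 4L) {
        stop("line ", ln, ": malformed term descriptor ", dQuote(fields[[2]]))
      }
      terms[[length(terms) + 1L]] <- tibble::tibble(
        id = id, term_class = m[[2]],
        start = as.integer(m[[3]]), end = as.integer(m[[4]]),
        surface = fields[[3]])
    } else if (grepl("^R[0-9]+$", id)) {
      if (length(fields) != 2L) {
        stop("line ", ln, ": malformed relation line (expected 2 tab fields)")
      }
      m <- regmatches(fields[[2]],
        regexec("^(\\S+) Arg1:(T[0-9]+) Arg2:(T[0-9]+)$", fields[[2]]))[[1]]
      if (length(m) != 4L) {
        stop("line ", ln, ": malformed relation descriptor ",
             dQuote(fields[[2]]))
      }
      rels[[length(rels) + 1L]] <- tibble::tibble(
        id = id, label = m[[2]], arg1 = m[[3]], arg2 = m[[4]])
    } else if (identical(id, "*")) {
      if (length(fields) != 2L || !startsWith(fields[[2]], "Equiv ")) {
        stop("line ", ln, ": malformed equivalence line")
      }
      members <- strsplit(sub("^Equiv ", "", fields[[2]]), " ",
                          fixed = TRUE)[[1]]
      if (length(members) < 2L || !all(grepl("^T[0-9]+$", members))) {
        stop("line ", ln, ": equivalence line needs >= 2 term ids")
      }
      equivs[[length(equivs) + 1L]] <- members
    } else {
      stop("line ", ln, ": unrecognized standoff line ", dQuote(line))
    }
  }
  abstract_annotation(
    doc_id, txt_document,
    terms = if (length(terms)) do.call(rbind, terms) else NULL,
    relations = if (length(rels)) do.call(rbind, rels) else NULL,
    equivs = equivs)
}

#' Serialize an annotation to standoff form
#'
#' Inverse of [parse_annotation()]: emits the `.txt` and `.ann` documents in
#' the same dialect, preserving mention/relation order, so that
#' `parse_annotation(write_annotation(a)$txt, write_annotation(a)$ann)`
#' reproduces `a`.
#'
#' @param a an [abstract_annotation()].
#' @return `list(txt = <text>, ann = <standoff document>)`.
#' @export
write_annotation <- function(a) {
  stopifnot(inherits(a, "ggprel_annotation"))
  t <- a$terms; r <- a$relations
  lines <- character(0)
  if (nrow(t)) {
    lines <- c(lines, sprintf("%s\t%s %d %d\t%s", t$id, t$term_class,
                              t$start, t$end, t$surface))
  }
  if (nrow(r)) {
    lines <- c(lines, sprintf("%s\t%s Arg1:%s Arg2:%s", r$id, r$label,
                              r$arg1, r$arg2))
  }
  for (g in a$equivs) {
    lines <- c(lines, paste0("*\tEquiv ", paste(g, collapse = " ")))
  }
  list(txt = a$text, ann = paste(lines, collapse = "\n"))
}

#' Read / write annotation files
#'
#' `read_annotation()` loads a `<doc_id>.txt` / `<doc_id>.ann` pair;
#' `write_annotation_files()` writes one.
#'
#' @param txt_path,ann_path file paths; `ann_path` defaults to `txt_path`
#'   with the extension replaced by `.ann`.
#' @param a an [abstract_annotation()].
#' @param dir output directory.
#' @return `read_annotation()` an [abstract_annotation()];
#'   `write_annotation_files()` the two paths, invisibly.
#' @export
read_annotation <- function(txt_path, ann_path = NULL) {
  if (is.null(ann_path)) ann_path <- sub("\\.txt$", ".ann", txt_path)
  for (p in c(txt_path, ann_path)) {
    if (!file.exists(p)) stop("annotation input not found: ", p)
  }
  txt <- paste(readLines(txt_path, encoding = "UTF-8", warn = FALSE),
               collapse = "\n")
  ann <- paste(readLines(ann_path, encoding = "UTF-8", warn = FALSE),
               collapse = "\n")
  doc_id <- sub("\\.txt$", "", basename(txt_path))
  parse_annotation(txt, ann, doc_id = doc_id)
}

#' @rdname read_annotation
#' @export
write_annotation_files <- function(a, dir) {
  out <- write_annotation(a)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  txt_path <- file.path(dir, paste0(a$doc_id, ".txt"))
  ann_path <- file.path(dir, paste0(a$doc_id, ".ann"))
  writeLines(out$txt, txt_path, useBytes = TRUE)
  writeLines(out$ann, ann_path, useBytes = TRUE)
  invisible(c(txt = txt_path, ann = ann_path))
}
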