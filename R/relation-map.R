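#' Load a relation-label mapping
#'
#' Reads the YAML file mapping standoff relation labels to formal relation
#' identifiers of the taxonomy, plus the GGP term classes, the kind list used
#' by the subclass pattern, and optional overrides of the variant
#' kind-restriction table. `default_relation_map()` loads the mapping shipped
#' with the package.
#'
#' @param path path to a `relation_map.yaml` file.
#' @return A list with elements `labels` (named character vector),
#'   `ggp_term_classes`, `kinds` and `kind_restrictions`.
#' @export
load_relation_map <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$labels) || length(raw$labels) == 0L) {
    stop("relation map at ", path, " defines no labels")
  }
  map <- list(
    labels = unlist(raw$labels),
    ggp_term_classes = as.character(raw$ggp_term_classes %||%
                                      c("Protein", "DNA", "RNA")),
    kinds = as.character(raw$kinds %||% c("DNA", "RNA", "Protein")),
    kind_restrictions = if (length(raw$kind_restrictions)) {
      unlist(raw$kind_restrictions)
    } else {
      character(0)
    }
  )
  map
}

#' @rdname load_relation_map
#' @export
default_relation_map <- function() {
  load_relation_map(system.file("extdata", "relation_map.yaml",
                                package = "ggprel", mustWork = TRUE))
}
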