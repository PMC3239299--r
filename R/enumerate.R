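#' Enumerate all finite models of a given signature and size
#'
#' Exhaustively yields every finite model over `n` named individuals with the
#' given class and relation signature: all `2^(n*c) * 2^(n^2*r)` combinations
#' of class memberships and relation edges. A combinatorial-explosion guard
#' refuses signatures whose model count exceeds `max_models`; use
#' [sample_models()] above that size.
#'
#' @param classes character vector of class identifiers.
#' @param relations character vector of relation identifiers.
#' @param n number of individuals (0 yields the single empty model).
#' @param max_models guard bound (default `2^16`).
#' @return List of [finite_model()] objects.
#' @examples
#' length(enumerate_models("C", "r", 1))  # 4
#' @export
enumerate_models <- function(classes, relations, n, max_models = 65536L) {
  stopifnot(n >= 0L)
  bits <- n * length(classes) + n * n * length(relations)
  total <- 2^bits
  if (total > max_models) {
    stop("enumeration of 2^", bits, " models exceeds the guard of ",
         max_models, " models; use sample_models() instead")
  }
  inds <- if (n > 0L) paste0("i", seq_len(n)) else character(0)
  grid_pairs <- if (n > 0L) {
    as.matrix(expand.grid(from = inds, to = inds,
                          stringsAsFactors = FALSE))[, c("from", "to"),
                                                     drop = FALSE]
  } else {
    matrix(character(0), ncol = 2L)
  }
  out <- vector("list", total)
  for (code in seq_len(total) - 1L) {
    rest <- code
    cls <- list()
    for (k in classes) {
      if (n > 0L) {
        sel <- bitwAnd(rest, 2^n - 1)
        rest <- rest %/% 2^n
        cls[[k]] <- inds[bitwAnd(sel %/% 2^(seq_len(n) - 1L), 1L) == 1L]
      } else {
        cls[[k]] <- character(0)
      }
    }
    rels <- list()
    np <- nrow(grid_pairs)
    for (r in relations) {
      if (np > 0L) {
        sel <- rest %% 2^np
        rest <- rest %/% 2^np
        pick <- bitwAnd(sel %/% 2^(seq_len(np) - 1L), 1L) == 1L
        rels[[r]] <- grid_pairs[pick, , drop = FALSE]
      } else {
        rels[[r]] <- matrix(character(0), ncol = 2L)
      }
    }
    out[[code + 1L]] <- finite_model(inds, class_ext = cls, rel_ext = rels)
  }
  out
}

#' Sample random finite models
#'
#' Seeded random models for property tests beyond the exhaustive-enumeration
#' guard: each class membership and each relation edge is included with
#' probability `density`. Reproducible for a fixed seed.
#'
#' @param classes,relations signature (character vectors).
#' @param n number of individuals.
#' @param k number of models to draw.
#' @param density inclusion probability (default 0.3).
#' @param seed integer seed.
#' @return List of [finite_model()] objects.
#' @export
sample_models <- function(classes, relations, n, k, density = 0.3,
                          seed = 1L) {
  stopifnot(n >= 0L, k >= 1L, density >= 0, density <= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  inds <- if (n > 0L) paste0("i", seq_len(n)) else character(0)
  lapply(seq_len(k), function(i) {
    cls <- lapply(classes, function(cc) inds[stats::runif(n) < density])
    names(cls) <- classes
    rels <- lapply(relations, function(r) {
      if (n == 0L) return(matrix(character(0), ncol = 2L))
      g <- expand.grid(from = inds, to = inds, stringsAsFactors = FALSE)
      g <- g[stats::runif(nrow(g)) < density, , drop = FALSE]
      as.matrix(g)
    })
    names(rels) <- relations
    finite_model(inds, class_ext = cls, rel_ext = rels)
  })
}
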