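test_that("the shipped taxonomy carries the prose-stated axiom flags", {
  tax <- genia_taxonomy()
  expect_setequal(tax$specs[["II-part-of"]]$flags,
                  c("REFLEXIVE", "TRANSITIVE", "ANTISYMMETRIC"))
  expect_setequal(tax$specs[["II-oc-part-of"]]$flags,
                  c("REFLEXIVE", "TRANSITIVE", "ANTISYMMETRIC",
                    "STRONG_SUPPLEMENTATION"))
  expect_setequal(tax$specs[["II-member-of"]]$flags,
                  c("IRREFLEXIVE", "ASYMMETRIC", "NON_TRANSITIVE"))
  expect_setequal(tax$specs[["II-has-variant"]]$flags,
                  c("REFLEXIVE", "SYMMETRIC", "NON_TRANSITIVE"))
  expect_setequal(tax$specs[["II-has-mutant"]]$flags,
                  c("IRREFLEXIVE", "SYMMETRIC", "NON_TRANSITIVE"))
  expect_identical(tax$specs[["II-member-of"]]$parent, "II-proper-part-of")
  expect_identical(tax$specs[["II-proper-part-of"]]$defined_from,
                   "II-part-of")
  expect_identical(tax$specs[["II-has-experimental-material"]]$flags,
                   character(0))
})

test_that("GGP-level relations resolve to II-level primitives", {
  tax <- genia_taxonomy()
  ggp <- Filter(function(s) s$level == "GGP", tax$specs)
  expect_gt(length(ggp), 0L)
  for (sp in ggp) {
    expect_false(is.null(sp$defined_from))
    expect_identical(tax$specs[[sp$defined_from]]$level, "II")
  }
  # variant sub-relations and their kind restrictions
  subs <- names(tax$specs)[vapply(tax$specs, function(s)
    identical(s$parent, "GGP-has-variant"), TRUE)]
  expect_length(subs, 6L)
  expect_identical(tax$specs[["GGP-has-isoform"]]$kind_restriction,
                   "Protein")
  expect_identical(tax$specs[["GGP-has-recombinant"]]$kind_restriction,
                   "DNA")
  expect_null(tax$specs[["GGP-has-experimental-material"]]$kind_restriction)
})

test_that("taxonomy parent links form a forest and exports are faithful", {
  tax <- genia_taxonomy()
  for (nm in names(tax$specs)) {
    seen <- nm
    cur <- tax$specs[[nm]]$parent
    while (!is.null(cur)) {
      expect_false(cur %in% seen)
      seen <- c(seen, cur)
      cur <- tax$specs[[cur]]$parent
    }
  }
  tb <- tibble::as_tibble(tax)
  expect_identical(nrow(tb), length(tax$specs))
  y <- yaml::yaml.load(taxonomy_yaml(tax))
  expect_setequal(names(y), names(tax$specs))
  expect_setequal(unlist(y[["II-part-of"]]$flags),
                  c("REFLEXIVE", "TRANSITIVE", "ANTISYMMETRIC"))
})

test_that("every shipped relation has jointly satisfiable flags", {
  tax <- genia_taxonomy()
  for (sp in tax$specs) {
    expect_length(validate_flags(sp), 0L)
  }
})

test_that("flag conflicts are reported as data", {
  c1 <- validate_flags(c("REFLEXIVE", "IRREFLEXIVE"))
  expect_length(c1, 1L)
  expect_setequal(c1[[1L]]$flags, c("REFLEXIVE", "IRREFLEXIVE"))
  c2 <- validate_flags(c("SYMMETRIC", "ANTISYMMETRIC", "IRREFLEXIVE"))
  expect_true(any(vapply(c2, function(x)
    identical(x$reason, "relation forced empty"), TRUE)))
})

test_that("flag-conflict analysis agrees with brute-force enumeration on a 2-element domain", {
  semantic <- c("REFLEXIVE", "IRREFLEXIVE", "SYMMETRIC", "ASYMMETRIC",
                "ANTISYMMETRIC", "TRANSITIVE")
  for (code in 0:63) {
    flags <- semantic[bitwAnd(code %/% 2^(0:5), 1L) == 1L]
    analytic_ok <- length(validate_flags(flags)) == 0L
    brute_ok <- brute_flags_nonempty_satisfiable(flags)
    expect_identical(analytic_ok, brute_ok,
                     info = paste(flags, collapse = "+"))
  }
})

test_that("a model realizing each spec's flags is accepted by the checker", {
  tax <- genia_taxonomy()
  # one concrete witness model per primitive with flags
  witness <- list(
    "II-part-of" = list(c("a", "a"), c("b", "b"), c("a", "b")),
    "II-member-of" = list(c("a", "b")),
    "II-has-variant" = list(c("a", "a"), c("b", "b"), c("a", "b"),
                            c("b", "a")),
    "II-has-mutant" = list(c("a", "b"), c("b", "a"))
  )
  for (rel in names(witness)) {
    m <- finite_model(c("a", "b"),
                      rel_ext = stats::setNames(list(witness[[rel]]), rel))
    flags <- tax$specs[[rel]]$flags
    ax <- lapply(setdiff(flags, "NON_TRANSITIVE"), function(f)
      ax_characteristic(rel, f))
    rep <- check(m, ax, taxonomy = NULL)
    expect_identical(nrow(rep), 0L, info = rel)
  }
})
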