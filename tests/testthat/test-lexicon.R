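test_that("the shipped dictionary has 134 design terms and validates", {
  v <- validate_lexicon(lex)
  expect_equal(v$n_terms, 134L)
  expect_setequal(v$nodes, c("observational", "trial", "review", "meta-analysis",
                             "miscellaneous"))
})

test_that("lookup of a surface form resolves design and node", {
  fac <- split_design_attributes(canonicalize("cross-sectional"), lex)
  expect_equal(fac$lower_level, "cross sectional")
  expect_equal(classify_high_level(fac$lower_level, lex), "observational")
})

test_that("the classification schema covers the enumerated lower-level designs", {
  ll <- lex$schema$lower_levels
  expect_true(all(c("descriptive", "cohort", "case control", "cross sectional",
                    "ecological", "quasi experimental", "case report",
                    "mendelian randomisation", "survey") %in% ll$observational))
  expect_true(all(c("individually randomised", "cluster randomised", "non randomised",
                    "controlled", "non controlled") %in% ll$trial))
  expect_true(all(c("systematic", "scoping", "meta-analytic", "investigation") %in% ll$review))
  expect_true(all(c("quantitative", "qualitative", "comparison") %in% ll$`meta-analysis`))
  # every lower level maps to exactly one node
  flat <- unlist(lapply(names(ll), function(n) setdiff(ll[[n]], lex$schema$qualifier_only)))
  expect_false(anyDuplicated(flat) > 0)
})

test_that("the attribute vocabulary covers the schema's attribute lists", {
  obs <- lex$attributes$attribute[lex$attributes$node == "observational"]
  expect_true(all(c("quantitative", "qualitative", "prospective", "retrospective",
                    "longitudinal", "nested", "propensity matched", "before after",
                    "time series", "interrupted time series", "serial", "secondary",
                    "survival", "case series", "exploratory", "follow up", "comparison",
                    "population based", "synthetic control", "difference in differences",
                    "natural experiment") %in% obs))
  tri <- lex$attributes$attribute[lex$attributes$node == "trial"]
  expect_true(all(c("non blinded", "single blind", "double blind", "triple blind",
                    "phase 1", "phase 2", "phase 3", "phase 4", "two arm", "multi arm",
                    "regulatory", "efficacy", "safety", "cost effectiveness",
                    "non inferiority", "superiority", "equivalence", "pilot",
                    "feasibility") %in% tri))
  # labels acting as both design and attribute are explicitly flagged
  expect_true(all(c("case series", "comparison") %in% lex$schema$dual_role))
})

test_that("every dictionary term factors to its declared design", {
  keys <- designminer:::canonical_key(lex$terms$term)
  derived <- vapply(keys, function(k) {
    f <- split_design_attributes(k, lex)
    if (nzchar(f$lower_level)) f$lower_level else "miscellaneous"
  }, character(1))
  expect_equal(unname(derived), lex$terms$canonical_design)
})

test_that("variant expansion follows the spelling/hyphen/plural rules", {
  expect_true("randomized controlled trial" %in% expand_variants("randomised controlled trial"))
  expect_true("case control" %in% expand_variants("case-control"))
  # full closure of a two-token term, enumerated by hand
  expect_setequal(expand_variants("meta-analysis"),
                  c("meta analysis", "meta-analysis", "meta analyses", "meta-analyses"))
})

test_that("variant expansion is idempotent", {
  for (term in c("randomised controlled trial", "case-control", "meta-analysis",
                 "cross sectional survey", "non randomised")) {
    once <- expand_variants(term)
    again <- sort(unique(unlist(lapply(once, expand_variants))))
    expect_equal(again, once, info = term)
  }
})

test_that("malformed lexicon configs are load errors, not silent defaults", {
  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines("version: 1", empty)
  expect_error(load_lexicon(empty), "empty")

  dup <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("version: 1",
               "nodes: [observational, miscellaneous]",
               "lower_levels: {observational: [cohort]}",
               "attributes: {observational: []}",
               "hierarchy: {unmappable_label: unmappable, tiers: [{name: cohort, members: [cohort]}]}",
               "terms:",
               "  - {term: cohort, canonical: cohort}",
               "  - {term: cohort, canonical: cohort}"), dup)
  expect_error(load_lexicon(dup), "duplicate")

  dangling <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("version: 1",
               "nodes: [observational, miscellaneous]",
               "lower_levels: {observational: [cohort]}",
               "attributes: {observational: []}",
               "hierarchy: {unmappable_label: unmappable, tiers: [{name: cohort, members: [cohort]}]}",
               "terms:",
               "  - {term: registry, canonical: registry}"), dangling)
  expect_error(load_lexicon(dangling), "registry")
})
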