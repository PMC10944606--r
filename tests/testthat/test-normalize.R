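test_that("canonicalization unifies case, spelling and hyphens, and is idempotent", {
  expect_equal(canonicalize("Randomized Controlled Trial"), "randomised controlled trial")
  expect_equal(canonicalize("cross sectional"), "cross sectional")
  expect_equal(canonicalize("meta analytic review"), "meta-analytic review")
  expect_equal(canonicalize("Nonrandomised controlled-trial"), "non randomised controlled trial")
  for (x in c(lex$terms$term, "Cross-Sectional Survey", "META-ANALYSES", "double blinded")) {
    expect_equal(canonicalize(canonicalize(x)), canonicalize(x), info = x)
  }
})

test_that("the lengthiest canonical mention becomes the representative", {
  mk <- function(s, st = seq_along(s) * 10L) tibble::tibble(surface = s, start = st)
  expect_equal(select_representative(mk(c("randomised double blinded controlled trial",
                                          "randomised controlled trial")))$surface,
               "randomised double blinded controlled trial")
  # measured after generic-token stripping: "cohort study" loses
  expect_equal(select_representative(mk(c("cohort study", "prospective cohort")))$surface,
               "prospective cohort")
  one <- mk("case report")
  expect_equal(select_representative(one)$surface, "case report")
  expect_error(select_representative(one[0, ]), "no design extracted")
})

test_that("representative selection is invariant to mention order", {
  set.seed(11)
  pool <- lex$terms$term
  for (i in 1:50) {
    n <- sample(2:6, 1)
    m <- tibble::tibble(surface = sample(pool, n), start = sample.int(500, n))
    ref <- select_representative(m)
    shuf <- m[sample.int(n), ]
    expect_equal(select_representative(shuf)$surface, ref$surface)
    expect_equal(select_representative(shuf)$start, ref$start)
  }
})

test_that("design/attribute factoring matches the classification schema", {
  f1 <- split_design_attributes("prospective cohort", lex)
  expect_equal(f1$lower_level, "cohort")
  expect_equal(f1$attributes, "prospective")

  f2 <- split_design_attributes("randomised double blinded controlled trial", lex)
  expect_equal(f2$lower_level, "randomised controlled")
  expect_equal(f2$attributes, "double blind")

  # compound lower levels are not over-factored
  f3 <- split_design_attributes("cross sectional descriptive", lex)
  expect_equal(f3$lower_level, "cross sectional descriptive")
  expect_length(f3$attributes, 0L)

  # unconsumed tokens force the miscellaneous route
  f4 <- split_design_attributes("analytical study", lex)
  expect_equal(f4$lower_level, "")
})

test_that("high-level classification routes designs and ambiguity correctly", {
  expect_equal(classify_high_level("systematic", lex), "review")
  expect_equal(classify_high_level("cluster randomised controlled", lex), "trial")
  expect_equal(classify_high_level("", lex), "miscellaneous")
  expect_equal(classify_high_level(split_design_attributes("systematic approach", lex)$lower_level, lex),
               "miscellaneous")
})

test_that("hierarchy mapping places designs and labels the unmappable", {
  expect_equal(map_to_hierarchy("meta-analysis", "meta-analysis", lex), "meta-analysis")
  expect_equal(lex$hierarchy$tiers[[1]]$name, "meta-analysis") # top tier
  expect_equal(map_to_hierarchy("cluster randomised controlled", "trial", lex),
               "randomised controlled trial")
  expect_equal(map_to_hierarchy("", "miscellaneous", lex), "unmappable")
  # "clinical study" is too ambiguous to place
  fac <- split_design_attributes(canonicalize("clinical study"), lex)
  expect_equal(map_to_hierarchy(fac$lower_level, classify_high_level(fac$lower_level, lex), lex),
               "unmappable")
  # meta-analysis above systematic review above RCT above observational tiers
  tiers <- vapply(lex$hierarchy$tiers, `[[`, character(1), "name")
  expect_lt(match("meta-analysis", tiers), match("systematic review", tiers))
  expect_lt(match("systematic review", tiers), match("randomised controlled trial", tiers))
  expect_lt(match("randomised controlled trial", tiers), match("cohort", tiers))
})

test_that("standardization yields one audited design per mentioned abstract", {
  syn <- generate_corpus(generator_config(n_abstracts = 60, seed = 5), lex)
  men <- extract_mentions(syn$corpus, rules, lex)
  sd <- assign_hierarchy(standardize_designs(men, lex), lex)
  expect_equal(anyDuplicated(sd$pmid), 0L)
  expect_setequal(sd$pmid, unique(men$pmid))
  # representative is the longest mention; attributes empty on miscellaneous
  for (i in seq_len(nrow(sd))) {
    lens <- designminer:::design_phrase_length(sd$all_mentions[[i]]$surface)
    expect_gte(designminer:::design_phrase_length(sd$representative_surface[i]), max(lens))
    if (sd$high_level[i] == "miscellaneous") expect_length(sd$attributes[[i]], 0L)
  }
  # exactly one hierarchy assignment each
  expect_false(any(is.na(sd$tier)))
})
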