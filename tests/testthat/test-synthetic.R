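test_that("generation is reproducible given the seed", {
  a <- generate_corpus(generator_config(n_abstracts = 30, seed = 17), lex)
  b <- generate_corpus(generator_config(n_abstracts = 30, seed = 17), lex)
  expect_identical(a$corpus$abstract_text, b$corpus$abstract_text)
  expect_identical(a$gold, b$gold)
  c <- generate_corpus(generator_config(n_abstracts = 30, seed = 18), lex)
  expect_false(identical(a$corpus$abstract_text, c$corpus$abstract_text))
})

test_that("injected designs are recoverable by a direct scan oracle", {
  syn <- generate_corpus(generator_config(n_abstracts = 100, seed = 1, p_no_design = 0.3), lex)
  bk <- syn$bookkeeping
  # gold set sizes equal the generator's own bookkeeping; ~70 expected
  n_design <- sum(!is.na(bk$design))
  expect_equal(sum(lengths(syn$gold$gold_designs)), n_design)
  expect_gt(n_design, 55)
  expect_lt(n_design, 85)
  # every injected design is present in its abstract text (scan, no rules)
  for (i in which(!is.na(bk$design))) {
    txt <- canonicalize(syn$corpus$abstract_text[syn$corpus$pmid == bk$pmid[i]])
    key <- bk$design[i]
    expect_match(txt, paste0("\\b", gsub("([][{}()+*^$|\\\\?.-])", "\\\\\\1", key), "\\b"),
                 info = bk$pmid[i])
  }
  # design-free abstracts contain no extractable design statement
  free <- syn$corpus$pmid %in% bk$pmid[is.na(bk$design)]
  men <- extract_mentions(syn$corpus[free, ], rules, lex)
  expect_equal(nrow(men), 0L)
})

test_that("forced duplicate mentions yield a full and a partial mention", {
  syn <- generate_corpus(generator_config(n_abstracts = 25, seed = 2, p_no_design = 0,
                                          p_duplicate_mention = 1, p_adversarial = 0), lex)
  men <- extract_mentions(syn$corpus, rules, lex)
  counts <- table(men$pmid)
  expect_true(all(counts >= 2))
  # both mentions relate to the single gold design
  res <- evaluate_corpus(syn$gold, men)
  expect_equal(res$counts$fp, 0L)
  expect_equal(res$counts$fn, 0L)
})

test_that("adversarial contexts are the negative rules' job", {
  cfg <- generator_config(n_abstracts = 80, seed = 4, p_adversarial = 1)
  syn <- generate_corpus(cfg, lex)
  men <- extract_mentions(syn$corpus, rules, lex)
  full <- evaluate_corpus(syn$gold, men)
  expect_equal(full$metrics$precision, 100)
  pos_only <- rules[rules$polarity == "positive", ]
  men2 <- extract_mentions(syn$corpus, pos_only, lex)
  broken <- evaluate_corpus(syn$gold, men2)
  expect_lt(broken$metrics$precision, 100)
})

test_that("prediction corruption returns the exact counts its coins imply", {
  syn <- generate_corpus(generator_config(n_abstracts = 50, seed = 6), lex)
  clean <- corrupt_predictions(syn$gold, fp_rate = 0, fn_rate = 0, seed = 1, lexicon = lex)
  expect_equal(clean$expected,
               list(tp = sum(lengths(syn$gold$gold_designs)), fp = 0L, fn = 0L))
  res <- evaluate_corpus(syn$gold, clean$predictions)
  expect_equal(res$counts, clean$expected)

  allfn <- corrupt_predictions(syn$gold, fp_rate = 0, fn_rate = 1, seed = 1, lexicon = lex)
  expect_equal(allfn$expected$tp, 0L)
  expect_equal(allfn$expected$fn, sum(lengths(syn$gold$gold_designs)))
})

test_that("generator configs validate probabilities and design weights", {
  expect_error(generator_config(p_no_design = 1.2), "\\[0, 1\\]")
  expect_error(generator_config(design_distribution = c(cohort = -1)), "non-negative")
  bad <- generator_config(design_distribution = c("hallway study" = 3))
  expect_error(generate_corpus(bad, lex), "unknown designs")
})

test_that("gold annotations round trip through JSON lines", {
  syn <- generate_corpus(generator_config(n_abstracts = 10, seed = 8), lex)
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_gold_jsonl(syn$gold, f)
  g2 <- read_gold_jsonl(f)
  expect_equal(g2$pmid, syn$gold$pmid)
  expect_equal(g2$gold_designs, syn$gold$gold_designs)
})
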