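test_that("PubMed XML ingestion keeps abstracts, reports skips, joins sections", {
  f <- withr::local_tempfile(fileext = ".xml")
  write_pubmed_fixture(f, list(
    list(pmid = "101", title = "T1",
         abstract = list(BACKGROUND = "Context here.",
                         METHODS = "We conducted a cross-sectional study.",
                         RESULTS = "Uptake was low."),
         year = 2001),
    list(pmid = "102", title = "No abstract"),
    list(pmid = "103", title = "T3", abstract = "Plain abstract.", year = 1999)
  ))
  expect_message(co <- read_pubmed_xml(f), "1 citation")
  expect_s3_class(co, "design_corpus")
  expect_equal(nrow(co), 2L)
  expect_equal(attr(co, "n_skipped"), 1L)
  expect_equal(attr(co, "skipped_pmids"), "102")
  # sections concatenated in document order, labels kept as uppercase prefixes
  expect_equal(co$abstract_text[co$pmid == "101"],
               "BACKGROUND: Context here. METHODS: We conducted a cross-sectional study. RESULTS: Uptake was low.")
  expect_equal(co$pub_year, c(2001L, 1999L))
})

test_that("duplicate PMIDs de-duplicate to first occurrence with a warning", {
  f <- withr::local_tempfile(fileext = ".xml")
  write_pubmed_fixture(f, list(
    list(pmid = "7", title = "first", abstract = "First version."),
    list(pmid = "7", title = "second", abstract = "Second version.")
  ))
  expect_warning(co <- read_pubmed_xml(f), "duplicate pmid")
  expect_equal(nrow(co), 1L)
  expect_equal(co$abstract_text, "First version.")
})

test_that("a citation without a PMID is a record-level error naming its index", {
  f <- withr::local_tempfile(fileext = ".xml")
  write_pubmed_fixture(f, list(
    list(pmid = "1", title = "ok", abstract = "Fine."),
    list(title = "broken", abstract = "No id.")
  ))
  expect_error(read_pubmed_xml(f), "citation 2")
})

test_that("MEDLINE flat text parses tags, continuations and empty files", {
  f <- withr::local_tempfile()
  writeLines(c("PMID- 1",
               "TI  - T",
               "AB  - we conducted a cross-sectional study",
               "      of X in prisons.",
               "DP  - 2001 Jan",
               "PT  - Journal Article",
               "LA  - eng"), f)
  co <- read_medline(f)
  expect_equal(co$pmid, "1")
  expect_equal(co$abstract_text, "we conducted a cross-sectional study of X in prisons.")
  expect_equal(co$pub_year, 2001L)
  expect_equal(co$pub_types[[1]], "Journal Article")

  f2 <- withr::local_tempfile()
  writeLines(character(0), f2)
  expect_equal(nrow(read_medline(f2)), 0L)

  f3 <- withr::local_tempfile()
  writeLines(c("TI  - orphan", "AB  - text"), f3)
  expect_error(read_medline(f3), "no PMID")
})

test_that("MEDLINE round trip preserves pmid, abstract and year; dialects agree", {
  f <- withr::local_tempfile(fileext = ".xml")
  write_pubmed_fixture(f, list(
    list(pmid = "11", title = "A", abstract = "This was a cohort study of X.", year = 1988),
    list(pmid = "12", title = "B", abstract = "We report a case series.", year = 2015)
  ))
  co <- read_pubmed_xml(f)
  ml <- withr::local_tempfile()
  write_medline(co, ml)
  co2 <- read_medline(ml)
  expect_equal(co$pmid, co2$pmid)
  expect_equal(co$abstract_text, co2$abstract_text)
  expect_equal(co$pub_year, co2$pub_year)

  # same citation hand-written in the MEDLINE dialect parses identically
  ml2 <- withr::local_tempfile()
  writeLines(c("PMID- 11", "TI  - A", "AB  - This was a cohort study of X.",
               "DP  - 1988", "LA  - eng"), ml2)
  co3 <- read_medline(ml2)
  expect_equal(co3$pmid, co$pmid[1])
  expect_equal(co3$abstract_text, co$abstract_text[1])
  expect_equal(co3$pub_year, co$pub_year[1])
})

test_that("JSON-lines corpus dump round trips", {
  f <- withr::local_tempfile(fileext = ".xml")
  write_pubmed_fixture(f, list(list(pmid = "5", title = "T", abstract = "Some text.", year = 2020)))
  co <- read_pubmed_xml(f)
  jl <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(co, jl)
  co2 <- read_corpus_jsonl(jl)
  expect_equal(co2$pmid, co$pmid)
  expect_equal(co2$abstract_text, co$abstract_text)
  expect_equal(co2$pub_year, co$pub_year)
})

test_that("corpus invariants reject empty abstracts and bad years", {
  expect_error(new_corpus(tibble::tibble(pmid = "1", abstract_text = "  ")), "non-empty")
  expect_error(new_corpus(tibble::tibble(pmid = "", abstract_text = "x")), "pmid")
  expect_error(new_corpus(tibble::tibble(pmid = "1", abstract_text = "x", pub_year = 1234)),
               "1900")
})

test_that("the stored PubMed query carries its defining clauses verbatim", {
  q <- pubmed_query()
  expect_true(grepl('epidemiology"[MeSH Terms]', q, fixed = TRUE))
  expect_true(grepl("synthetic control", q, fixed = TRUE))
  expect_true(startsWith(q, "prison OR borstal OR jail"))
})
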