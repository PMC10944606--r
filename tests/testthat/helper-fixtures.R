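# shared fixtures: the shipped lexicon/rules, loaded once per test run
lex <- load_lexicon()
rules <- load_rules()

# minimal two-dialect citation fixtures built in code
write_pubmed_fixture <- function(path, citations) {
  body <- vapply(citations, function(ct) {
    abs_xml <- if (is.null(ct$abstract)) "" else {
      if (is.list(ct$abstract)) {
        paste0("<Abstract>",
               paste(vapply(names(ct$abstract), function(lab) {
                 sprintf('<AbstractText Label="%s">%s</AbstractText>', lab, ct$abstract[[lab]])
               }, character(1)), collapse = ""),
               "</Abstract>")
      } else sprintf("<Abstract><AbstractText>%s</AbstractText></Abstract>", ct$abstract)
    }
    pmid_xml <- if (is.null(ct$pmid)) "" else sprintf("<PMID>%s</PMID>", ct$pmid)
    yr <- if (is.null(ct$year)) "" else
      sprintf("<Journal><JournalIssue><PubDate><Year>%s</Year></PubDate></JournalIssue></Journal>", ct$year)
    sprintf(paste0("<PubmedArticle><MedlineCitation>%s<Article>",
                   "<ArticleTitle>%s</ArticleTitle>%s<Language>eng</Language>%s",
                   "</Article></MedlineCitation></PubmedArticle>"),
            pmid_xml, ct$title %||% "Untitled", abs_xml, yr)
  }, character(1))
  writeLines(c('<?xml version="1.0"?>', "<PubmedArticleSet>", body, "</PubmedArticleSet>"),
             path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent oracle: exhaustive regex scan for expected surfaces in a text,
# returning 0-based half-open spans (no rule logic involved)
oracle_spans <- function(text, surface) {
  m <- gregexpr(paste0("(?i)\\b", gsub("([][{}()+*^$|\\\\?.-])", "\\\\\\1", surface), "\\b"),
                text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) + attr(m, "match.length") - 1L)
}
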