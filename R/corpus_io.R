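#' Construct a validated abstract corpus
#'
#' A corpus is a tibble with one row per citation and columns `pmid`, `title`,
#' `abstract_text`, `pub_year`, `pub_types` (list-column) and `language`.
#' Invariants enforced here: non-empty unique PMIDs, non-empty abstract text
#' (records admitted to extraction must have an abstract), and `pub_year`
#' either `NA` or a four-digit integer >= 1900.
#'
#' @param records data frame with at least `pmid` and `abstract_text`;
#'   missing optional columns are filled.
#' @param source_description provenance string stored as an attribute.
#' @param n_skipped number of input citations dropped for lacking an abstract.
#' @param skipped_pmids identifiers of the dropped citations.
#' @return a tibble of class `design_corpus`.
#' @export
new_corpus <- function(records, source_description = "unspecified",
                       n_skipped = 0L, skipped_pmids = character(0)) {
  records <- tibble::as_tibble(records)
  if (nrow(records) > 0L) {
    if (!all(c("pmid", "abstract_text") %in% names(records))) {
      stop("corpus records need at least 'pmid' and 'abstract_text'", call. = FALSE)
    }
  } else {
    records <- tibble::tibble(pmid = character(0), title = character(0),
                              abstract_text = character(0), pub_year = integer(0),
                              pub_types = list(), language = character(0))
  }
  if (!"title" %in% names(records)) records$title <- NA_character_
  if (!"pub_year" %in% names(records)) records$pub_year <- NA_integer_
  if (!"pub_types" %in% names(records)) records$pub_types <- vector("list", nrow(records))
  if (!"language" %in% names(records)) records$language <- NA_character_
  records$pmid <- as.character(records$pmid)
  records$pub_year <- as.integer(records$pub_year)
  if (!is.list(records$pub_types)) records$pub_types <- as.list(records$pub_types)

  if (any(is.na(records$pmid) | !nzchar(records$pmid))) {
    stop("every record must carry a non-empty pmid", call. = FALSE)
  }
  dup <- duplicated(records$pmid)
  if (any(dup)) {
    warning(sprintf("dropping %d duplicate pmid(s), keeping first occurrence: %s",
                    sum(dup), paste(unique(records$pmid[dup]), collapse = ", ")),
            call. = FALSE)
    records <- records[!dup, , drop = FALSE]
  }
  if (any(is.na(records$abstract_text) | !nzchar(trimws(records$abstract_text)))) {
    stop("corpus records must have non-empty abstract_text", call. = FALSE)
  }
  yr <- records$pub_year
  bad_year <- !is.na(yr) & (yr < 1900L | yr > 9999L)
  if (any(bad_year)) {
    stop(sprintf("pub_year must be a 4-digit year >= 1900; offending pmid(s): %s",
                 paste(records$pmid[bad_year], collapse = ", ")), call. = FALSE)
  }
  records <- records[, c("pmid", "title", "abstract_text", "pub_year", "pub_types", "language")]
  structure(records,
            class = c("design_corpus", class(tibble::tibble())),
            source_description = source_description,
            n_skipped = as.integer(n_skipped),
            skipped_pmids = skipped_pmids)
}

#' @export
print.design_corpus <- function(x, ...) {
  cat(sprintf("<design_corpus> %d record(s); source: %s; skipped (no abstract): %d\n",
              nrow(x), attr(x, "source_description"), attr(x, "n_skipped")))
  NextMethod()
}

#' Read a PubMed XML export into a corpus
#'
#' Parses the `PubmedArticleSet` dialect. Citations without an `AbstractText`
#' are counted and reported via the corpus skip attributes rather than
#' silently dropped. Structured abstracts are concatenated in document order
#' with their section labels preserved as `"LABEL: text"` prefixes, because
#' anchor patterns legitimately match inside labelled METHODS sections.
#'
#' @param path path to a PubMed XML file.
#' @return a [new_corpus()] tibble.
#' @export
read_pubmed_xml <- function(path) {
  doc <- xml2::read_xml(path) # malformed XML -> xml2 error with line/column
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle | .//MedlineCitation[not(ancestor::PubmedArticle)]")
  if (length(arts) == 0L) {
    return(new_corpus(tibble::tibble(), source_description = sprintf("pubmed-xml:%s", path)))
  }
  recs <- lapply(seq_along(arts), function(i) {
    art <- arts[[i]]
    pmid <- xml2::xml_text(xml2::xml_find_first(art, ".//MedlineCitation/PMID | ./PMID"))
    if (is.na(pmid) || !nzchar(pmid)) {
      stop(sprintf("citation %d has no PMID", i), call. = FALSE)
    }
    title <- xml2::xml_text(xml2::xml_find_first(art, ".//ArticleTitle"))
    abs_nodes <- xml2::xml_find_all(art, ".//Abstract/AbstractText")
    abstract <- if (length(abs_nodes) == 0L) NA_character_ else {
      parts <- vapply(abs_nodes, function(n) {
        lab <- xml2::xml_attr(n, "Label")
        txt <- xml2::xml_text(n)
        if (!is.na(lab) && nzchar(lab)) paste0(toupper(lab), ": ", txt) else txt
      }, character(1))
      paste(parts, collapse = " ")
    }
    year <- xml2::xml_text(xml2::xml_find_first(art, ".//Journal//PubDate/Year"))
    if (is.na(year)) {
      md <- xml2::xml_text(xml2::xml_find_first(art, ".//Journal//PubDate/MedlineDate"))
      year <- stringr::str_extract(md, "\\b(19|20)\\d{2}\\b")
    }
    ptypes <- xml2::xml_text(xml2::xml_find_all(art, ".//PublicationTypeList/PublicationType"))
    lang <- xml2::xml_text(xml2::xml_find_first(art, ".//Language"))
    tibble::tibble(pmid = pmid, title = title, abstract_text = abstract,
                   pub_year = suppressWarnings(as.integer(year)),
                   pub_types = list(ptypes), language = lang)
  })
  recs <- do.call(rbind, recs)
  has_abs <- !is.na(recs$abstract_text) & nzchar(trimws(recs$abstract_text))
  skipped <- recs$pmid[!has_abs]
  if (length(skipped) > 0L) {
    message(sprintf("read_pubmed_xml: %d citation(s) without AbstractText skipped: %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  }
  new_corpus(recs[has_abs, , drop = FALSE],
             source_description = sprintf("pubmed-xml:%s", path),
             n_skipped = length(skipped), skipped_pmids = skipped)
}

#' Read a MEDLINE flat-text export into a corpus
#'
#' Parses the tagged MEDLINE dialect (`PMID-`, `TI  -`, `AB  -`, `DP  -`,
#' `PT  -`, `LA  -`); continuation lines (indented by spaces) are joined with
#' a single space. `DP` is parsed to `pub_year` by its leading 4-digit year.
#'
#' @param path path to a MEDLINE text file.
#' @return a [new_corpus()] tibble.
#' @export
read_medline <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  src <- sprintf("medline:%s", path)
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    return(new_corpus(tibble::tibble(), source_description = src))
  }
  # split into records on blank lines
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(c(TRUE, blank[-length(blank)])) # record id per line
  recs_raw <- split(lines[!blank], grp[!blank])
  parse_one <- function(rl, idx) {
    tags <- character(0); vals <- character(0)
    for (ln in rl) {
      if (grepl("^[A-Z0-9]{1,4}\\s*- ", ln)) {
        tag <- trimws(sub("^([A-Z0-9]{1,4})\\s*- .*$", "\\1", ln))
        val <- sub("^[A-Z0-9]{1,4}\\s*- ", "", ln)
        tags <- c(tags, tag); vals <- c(vals, val)
      } else if (grepl("^\\s+", ln) && length(vals) > 0L) {
        vals[length(vals)] <- paste(vals[length(vals)], trimws(ln))
      }
    }
    pmid <- vals[tags == "PMID"][1]
    if (is.na(pmid) || !nzchar(trimws(pmid))) {
      stop(sprintf("MEDLINE record %d has no PMID tag", idx), call. = FALSE)
    }
    dp <- vals[tags == "DP"][1]
    year <- if (is.na(dp)) NA_character_ else stringr::str_extract(dp, "^\\s*\\d{4}")
    ab <- vals[tags == "AB"]
    tibble::tibble(
      pmid = trimws(pmid),
      title = if (any(tags == "TI")) vals[tags == "TI"][1] else NA_character_,
      abstract_text = if (length(ab) > 0L) ab[1] else NA_character_,
      pub_year = suppressWarnings(as.integer(trimws(year))),
      pub_types = list(vals[tags == "PT"]),
      language = if (any(tags == "LA")) vals[tags == "LA"][1] else NA_character_
    )
  }
  recs <- do.call(rbind, Map(parse_one, recs_raw, seq_along(recs_raw)))
  has_abs <- !is.na(recs$abstract_text) & nzchar(trimws(recs$abstract_text))
  skipped <- recs$pmid[!has_abs]
  if (length(skipped) > 0L) {
    message(sprintf("read_medline: %d record(s) without AB skipped: %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  }
  new_corpus(recs[has_abs, , drop = FALSE], source_description = src,
             n_skipped = length(skipped), skipped_pmids = skipped)
}

#' Write a corpus in MEDLINE flat-text format
#'
#' Inverse of [read_medline()]: round-tripping preserves `pmid`,
#' `abstract_text` and `pub_year` for all records.
#'
#' @param corpus a [new_corpus()] tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_medline <- function(corpus, path) {
  blocks <- vapply(seq_len(nrow(corpus)), function(i) {
    r <- corpus[i, ]
    out <- c(sprintf("PMID- %s", r$pmid))
    if (!is.na(r$title)) out <- c(out, sprintf("TI  - %s", r$title))
    out <- c(out, sprintf("AB  - %s", r$abstract_text))
    if (!is.na(r$pub_year)) out <- c(out, sprintf("DP  - %d", r$pub_year))
    for (pt in r$pub_types[[1]]) out <- c(out, sprintf("PT  - %s", pt))
    if (!is.na(r$language)) out <- c(out, sprintf("LA  - %s", r$language))
    paste(out, collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path, useBytes = TRUE)
  invisible(path)
}

#' Read / write a corpus as JSON lines
#'
#' @param corpus a corpus tibble.
#' @param path file path.
#' @return `read_corpus_jsonl()` returns a [new_corpus()] tibble;
#'   `write_corpus_jsonl()` returns `path` invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  write_jsonl(corpus, path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  x <- read_jsonl(path)
  if (nrow(x) == 0L) return(new_corpus(tibble::tibble(), source_description = sprintf("jsonl:%s", path)))
  new_corpus(x, source_description = sprintf("jsonl:%s", path))
}

#' The PubMed query defining the epidemiological criminology corpus
#'
#' Returns, verbatim, the boolean PubMed query (offender/prison terms combined
#' with the "epidemiology" MeSH heading, publication types and
#' randomisation/natural-experiment terms) used to assemble the source corpus.
#' Useful for re-running the search against live PubMed.
#'
#' @return a single query string.
#' @export
pubmed_query <- function() {
  paste0(
    "prison OR borstal OR jail OR jails OR gaol OR gaols OR penitentiary OR ",
    "custody OR custodial OR (corrective AND (service or services)) OR ",
    "((correctional or detention) AND (centre or centres OR center OR centers ",
    "OR complex OR complexes or facility or facilities)) OR (closed AND ",
    "(setting)) OR prisoner OR prisoners OR incarcerated OR criminals OR ",
    "criminal OR felon OR felons OR remandee OR remandees OR delinquent OR ",
    "delinquents OR detainee OR detainees OR convict OR convicts OR cellmate ",
    "OR cellmates OR offenders OR offender OR ((young OR adolescent) AND ",
    "(offender OR offenders)) OR ((delinquent OR incarcerated) AND youth) OR ",
    "(juvenile AND (delinquents OR delinquent OR delinquency OR detainee OR ",
    "detainees OR offender OR offenders)) OR ((young) AND (people) AND (in) ",
    "AND (custody)) OR ((justice) AND (involved) AND (youth)) OR ",
    "((incarcerated) AND (young) AND (people OR person OR persons)) OR ",
    "((juvenile OR juveniles) AND (in) AND (custody)) AND english[lang] AND ",
    "(\"epidemiology\"[Subheading] OR \"epidemiology\"[MeSH Terms] OR ",
    "epidemiology[Text Word] OR clinical study[publication type] OR ",
    "case reports[publication type] OR clinical trial[publication type] OR ",
    "clinical trial, phase i[publication type] OR clinical trial, phase ii",
    "[publication type] OR clinical trial, phase iii[publication type] OR ",
    "clinical trial, phase iv[publication type] OR comparative study",
    "[publication type] OR controlled clinical trial[publication type] OR ",
    "evaluation study[publication type] OR meta-analysis[publication type] OR ",
    "multicenter study[publication type] OR observational study",
    "[publication type] OR pragmatic clinical trial[publication type] OR ",
    "randomised controlled trial[publication type] OR review",
    "[publication type] OR systematic review[publication type] OR twin study",
    "[publication type] OR validation study[publication type] OR ",
    "non randomised trial[text word] OR non randomised trial[text word] OR ",
    "randomization experiment OR randomisation experiment OR ",
    "natural experiment OR synthetic control"
  )
}
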