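#' Frequency table of standardized designs
#'
#' Tabulates counts and one-decimal truncated percentages of an explicit
#' denominator -- stated rather than implied, because published proportions in
#' this area are only reproducible when the denominator is known. The first
#' row reports the total number of abstracts with any extracted design.
#'
#' @param designs a [standardize_designs()] tibble.
#' @param denominator the count percentages are taken over (e.g. total corpus
#'   size, or the with-design total); must be positive and at least the number
#'   of designs.
#' @param by `"high"` tabulates the five high-level nodes; `"lower"` the
#'   lower-level designs (with their node attached).
#' @return tibble with `label`, `high_level`, `n`, `pct` plus a `denominator`
#'   attribute; percents recompute from `n` via [pct_of()].
#' @export
tabulate_designs <- function(designs, denominator, by = c("high", "lower")) {
  by <- match.arg(by)
  if (length(denominator) != 1L || denominator <= 0) {
    stop("denominator must be a single positive count", call. = FALSE)
  }
  if (denominator < nrow(designs)) {
    stop("denominator is smaller than the number of designs", call. = FALSE)
  }
  total <- tibble::tibble(label = "any design", high_level = NA_character_,
                          n = nrow(designs), pct = pct_of(nrow(designs), denominator))
  if (nrow(designs) == 0L) {
    out <- total
  } else if (by == "high") {
    tab <- table(factor(designs$high_level,
                        levels = c("observational", "review", "trial",
                                   "meta-analysis", "miscellaneous")))
    out <- rbind(total, tibble::tibble(label = names(tab), high_level = names(tab),
                                       n = as.integer(tab),
                                       pct = pct_of(as.integer(tab), denominator)))
  } else {
    lab <- ifelse(nzchar(designs$lower_level), designs$lower_level, "(miscellaneous)")
    agg <- stats::aggregate(list(n = lab), by = list(label = lab, high_level = designs$high_level),
                            FUN = length)
    agg <- agg[order(-agg$n, agg$label), , drop = FALSE]
    out <- rbind(total, tibble::tibble(label = agg$label, high_level = agg$high_level,
                                       n = as.integer(agg$n),
                                       pct = pct_of(as.integer(agg$n), denominator)))
  }
  attr(out, "denominator") <- denominator
  out
}

#' Frequency table of attributes within one high-level node
#'
#' Counts attributes among the designs of `node` that carry at least one
#' attribute; the denominator is the number of such attribute-bearing designs
#' (stated explicitly in the output). A design can contribute several
#' attributes, so percentages need not sum to 100.
#'
#' @param designs a [standardize_designs()] tibble.
#' @param node one of the high-level nodes.
#' @return tibble with `attribute`, `n`, `pct` and a `denominator` attribute.
#' @export
tabulate_attributes <- function(designs, node) {
  lex_nodes <- c("observational", "trial", "review", "meta-analysis", "miscellaneous")
  if (!node %in% lex_nodes) stop(sprintf("unknown node '%s'", node), call. = FALSE)
  sel <- designs[designs$high_level == node &
                   vapply(designs$attributes, length, integer(1)) > 0L, , drop = FALSE]
  denom <- nrow(sel)
  if (denom == 0L) {
    out <- tibble::tibble(attribute = character(0), n = integer(0), pct = numeric(0))
    attr(out, "denominator") <- 0L
    return(out)
  }
  tab <- sort(table(unlist(sel$attributes)), decreasing = TRUE)
  out <- tibble::tibble(attribute = names(tab), n = as.integer(tab),
                        pct = pct_of(as.integer(tab), denom))
  attr(out, "denominator") <- denom
  out
}

#' Yearly trend of articles, extracted designs and hierarchy tiers
#'
#' @param designs a [assign_hierarchy()] tibble (must carry `tier`).
#' @param corpus the corpus the designs came from (provides `pub_year`).
#' @param year_range optional inclusive year span; records outside it are
#'   excluded with a warning.
#' @return tibble with one row per (year, category): `year`, `category`
#'   (`"articles"`, `"with design"`, or a tier name), `count` and `proportion`
#'   (truncated percent of that year's designs; `NA` for the two bookkeeping
#'   categories). Tier proportions within a year sum to 100 up to truncation
#'   slack.
#' @export
trend_by_year <- function(designs, corpus, year_range = NULL) {
  if (!"tier" %in% names(designs)) {
    stop("designs must carry a 'tier' column; run assign_hierarchy() first", call. = FALSE)
  }
  years <- corpus$pub_year
  keep <- !is.na(years)
  if (!is.null(year_range)) {
    inside <- keep & years >= year_range[1] & years <= year_range[2]
    if (any(keep & !inside)) {
      warning(sprintf("%d record(s) outside year range excluded", sum(keep & !inside)),
              call. = FALSE)
    }
    keep <- inside
  }
  corpus <- corpus[keep, , drop = FALSE]
  designs <- designs[designs$pmid %in% corpus$pmid, , drop = FALSE]
  dyear <- corpus$pub_year[match(designs$pmid, corpus$pmid)]
  rows <- list()
  for (y in sort(unique(corpus$pub_year))) {
    n_art <- sum(corpus$pub_year == y)
    d <- designs[dyear == y, , drop = FALSE]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      year = y, category = c("articles", "with design"),
      count = c(n_art, nrow(d)), proportion = NA_real_)
    if (nrow(d) > 0L) {
      tab <- table(d$tier)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        year = y, category = names(tab), count = as.integer(tab),
        proportion = pct_of(as.integer(tab), nrow(d)))
    }
  }
  do.call(rbind, rows)
}

#' Read / write gold annotations as JSON lines
#'
#' One object per abstract: `{"pmid": ..., "gold_designs": [...]}`.
#'
#' @param gold tibble with `pmid` and `gold_designs` list-column.
#' @param path file path.
#' @return `read_gold_jsonl()` returns the gold tibble; the writer returns
#'   `path` invisibly.
#' @export
write_gold_jsonl <- function(gold, path) {
  write_jsonl(gold, path)
}

#' @rdname write_gold_jsonl
#' @export
read_gold_jsonl <- function(path) {
  x <- read_jsonl(path)
  if (nrow(x) == 0L) return(tibble::tibble(pmid = character(0), gold_designs = list()))
  gd <- x$gold_designs
  if (!is.list(gd)) gd <- as.list(gd)
  gd <- lapply(gd, function(v) {
    v <- unlist(v)
    if (is.null(v) || all(is.na(v))) character(0) else as.character(v)
  })
  tibble::tibble(pmid = as.character(x$pmid), gold_designs = gd)
}
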