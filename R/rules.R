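default_rules_path <- function() {
  system.file("extdata", "design_rules.yaml", package = "designminer", mustWork = TRUE)
}

#' Load the syntactic pattern rules
#'
#' Rules are data, not code: each rule has an `id`, a `polarity` (`positive`
#' rules extract, `negative` rules suppress), a regex `anchor` of semi-frozen
#' lexical expressions (e.g. variants of "we conducted a"), a `position`
#' stating whether the anchor precedes (`before`) or follows (`after`) the
#' design slot, a token `window` between anchor and slot, and optionally
#' `after_req`, a regex that must match immediately after the slot (used for
#' patterns like "this <design> study"). The design slot itself is always a
#' dictionary term; a rule may restrict it with `slot_canon`.
#'
#' @param path rule config file (YAML); defaults to the shipped rule set
#'   (20 positive rules, 3 negative-context rules).
#' @return tibble of class `design_rules`, ordered by `id` (rules are
#'   priority-ordered: ties for the same slot resolve to the lowest id).
#' @export
load_rules <- function(path = default_rules_path()) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$rules) || length(cfg$rules) == 0L) {
    stop("rule config is empty", call. = FALSE)
  }
  rules <- do.call(rbind, lapply(cfg$rules, function(r) {
    tibble::tibble(
      id = r$id,
      polarity = r$polarity %||% "positive",
      position = r$position %||% "before",
      anchor = r$anchor,
      window = as.integer(r$window %||% 6L),
      after_req = r$after_req %||% NA_character_,
      slot_canon = r$slot_canon %||% NA_character_
    )
  }))
  if (anyDuplicated(rules$id)) {
    stop(sprintf("duplicate rule id(s): %s",
                 paste(unique(rules$id[duplicated(rules$id)]), collapse = ", ")),
         call. = FALSE)
  }
  if (!all(rules$polarity %in% c("positive", "negative"))) {
    stop("rule polarity must be 'positive' or 'negative'", call. = FALSE)
  }
  if (!all(rules$position %in% c("before", "after"))) {
    stop("rule position must be 'before' or 'after'", call. = FALSE)
  }
  rules <- rules[order(rules$id), , drop = FALSE]
  class(rules) <- c("design_rules", class(rules))
  rules
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a rule set against a lexicon
#'
#' @param rules a [load_rules()] tibble.
#' @param lexicon a [load_lexicon()] object.
#' @return list with positive/negative rule counts, unreachable rules (whose
#'   `slot_canon` names no lexicon design) and pairs of rules sharing an
#'   identical anchor (overlap warnings).
#' @export
validate_rules <- function(rules, lexicon) {
  unreachable <- character(0)
  for (i in seq_len(nrow(rules))) {
    sc <- rules$slot_canon[i]
    if (!is.na(sc) && !sc %in% canonical_key(lexicon$terms$term)) {
      unreachable <- c(unreachable, rules$id[i])
    }
  }
  dup_anchor <- rules$anchor[duplicated(rules$anchor)]
  overlaps <- unique(rules$id[rules$anchor %in% dup_anchor])
  res <- list(
    n_rules = nrow(rules),
    n_positive = sum(rules$polarity == "positive"),
    n_negative = sum(rules$polarity == "negative"),
    unreachable = unreachable,
    overlapping_anchors = overlaps
  )
  class(res) <- "rules_validation"
  res
}

#' @export
print.rules_validation <- function(x, ...) {
  cat(sprintf("rule set: %d rules (%d positive, %d negative)\n",
              x$n_rules, x$n_positive, x$n_negative))
  if (length(x$unreachable)) {
    cat("unreachable rules (slot not in lexicon):", paste(x$unreachable, collapse = ", "), "\n")
  }
  if (length(x$overlapping_anchors)) {
    cat("rules sharing an anchor:", paste(x$overlapping_anchors, collapse = ", "), "\n")
  }
  invisible(x)
}

# abbreviations that never terminate a sentence (token preceding the period)
.abbrev <- c("e.g", "i.e", "vs", "cf", "al", "etc", "approx", "fig", "figs",
             "no", "dr", "mr", "mrs", "ms", "st", "ca", "resp")

#' Segment text into sentence spans
#'
#' Splits on sentence-final punctuation followed by whitespace and an
#' uppercase letter or digit, guarding common abbreviations ("e.g.", "vs.",
#' "i.e.", single initials). Spans are 0-based, half-open, ordered,
#' non-overlapping, and cover all non-whitespace characters.
#'
#' @param text a single string.
#' @return tibble with `start`, `end` (0-based half-open) and `sentence`.
#' @export
segment_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  cand <- gregexpr("[.!?]+(?=\\s)", text, perl = TRUE)[[1]]
  breaks <- integer(0)
  if (cand[1] != -1L) {
    lens <- attr(cand, "match.length")
    for (k in seq_along(cand)) {
      pos <- cand[k]              # position of punctuation (1-based)
      endp <- pos + lens[k] - 1L  # last punctuation char
      before <- substr(text, max(1L, pos - 12L), pos - 1L)
      prev_tok <- stringr::str_extract(before, "[A-Za-z.]+$")
      prev_word <- tolower(sub("\\.$", "", prev_tok %||% ""))
      if (!is.na(prev_word) && (prev_word %in% .abbrev || grepl("^[a-z]$", prev_word))) next
      rest <- substr(text, endp + 1L, nchar(text))
      if (!grepl("^\\s+[\"'(\\[]?[A-Z0-9]", rest)) next
      breaks <- c(breaks, endp)
    }
  }
  starts1 <- c(1L, breaks + 1L)
  ends1 <- c(breaks, nchar(text))
  out <- lapply(seq_along(starts1), function(i) {
    s <- starts1[i]; e <- ends1[i]
    seg <- substr(text, s, e)
    lead <- nchar(seg) - nchar(sub("^\\s+", "", seg))
    trail <- nchar(seg) - nchar(sub("\\s+$", "", seg))
    s <- s + lead; e <- e - trail
    if (e < s) return(NULL)
    tibble::tibble(start = s - 1L, end = e, sentence = substr(text, s, e))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  out
}

# locate all dictionary matches in one sentence; returns tibble of 1-based
# local [start, end] positions plus resolved term row
locate_terms <- function(sentence, lexicon) {
  m <- gregexpr(lexicon$matcher$regex, sentence, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          surface = character(0), term_row = integer(0)))
  }
  len <- attr(m, "match.length")
  surface <- substring(sentence, m, m + len - 1L)
  tibble::tibble(start = as.integer(m), end = as.integer(m + len - 1L),
                 surface = surface, term_row = lookup_term(surface, lexicon))
}

# tokens strictly between two 1-based positions (end_a exclusive bound side)
gap_tokens <- function(sentence, from, to) {
  if (to <= from) return(0L)
  n_tokens(substr(sentence, from, to))
}

#' Apply pattern rules to one abstract
#'
#' Scans the abstract sentence by sentence (mentions never cross sentence
#' boundaries). Every positive-rule anchor that has a dictionary design term
#' within its token window yields a mention; negative-context rules then veto
#' any mention inside their window (prior-study references such as "follow up
#' of a randomised controlled trial"). Duplicate (surface, span) pairs are
#' collapsed to the lowest rule id; the same design at different spans is
#' kept. Matching is deterministic.
#'
#' @param text abstract text (or a single-row corpus record).
#' @param rules a [load_rules()] tibble.
#' @param lexicon a [load_lexicon()] object.
#' @return mention tibble: `surface`, `start`, `end` (0-based half-open
#'   character span in the abstract text), `rule_id`, `term`,
#'   `canonical_design`, `sentence_index`.
#' @export
apply_rules <- function(text, rules, lexicon) {
  if (is.data.frame(text)) text <- text$abstract_text[1]
  stopifnot(is.character(text), length(text) == 1L)
  empty <- tibble::tibble(surface = character(0), start = integer(0),
                          end = integer(0), rule_id = character(0),
                          term = character(0), canonical_design = character(0),
                          sentence_index = integer(0))
  if (!nzchar(trimws(text))) return(empty)
  sents <- segment_sentences(text)
  pos_rules <- rules[rules$polarity == "positive", , drop = FALSE]
  neg_rules <- rules[rules$polarity == "negative", , drop = FALSE]
  hits <- list()
  for (si in seq_len(nrow(sents))) {
    sent <- sents$sentence[si]
    slots <- locate_terms(sent, lexicon)
    slots <- slots[!is.na(slots$term_row), , drop = FALSE]
    if (nrow(slots) == 0L) next
    matched <- rep(NA_character_, nrow(slots)) # rule id per slot, lowest wins
    for (ri in seq_len(nrow(pos_rules))) {
      sel <- match_rule_slots(sent, pos_rules[ri, ], slots, lexicon)
      for (sl in sel) {
        if (is.na(matched[sl])) matched[sl] <- pos_rules$id[ri]
      }
    }
    vetoed <- rep(FALSE, nrow(slots))
    for (ri in seq_len(nrow(neg_rules))) {
      sel <- match_rule_slots(sent, neg_rules[ri, ], slots, lexicon, all_in_window = TRUE)
      vetoed[sel] <- TRUE
    }
    keep <- which(!is.na(matched) & !vetoed)
    if (length(keep) == 0L) next
    k <- slots[keep, , drop = FALSE]
    hits[[length(hits) + 1L]] <- tibble::tibble(
      surface = k$surface,
      start = sents$start[si] + k$start - 1L,      # 0-based
      end = sents$start[si] + k$end,               # half-open
      rule_id = matched[keep],
      term = lexicon$terms$term[k$term_row],
      canonical_design = lexicon$terms$canonical_design[k$term_row],
      sentence_index = si
    )
  }
  if (length(hits) == 0L) return(empty)
  out <- do.call(rbind, hits)
  out <- out[!duplicated(out[, c("start", "end")]), , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

# slots selected by one rule in one sentence. For positive 'before' rules the
# nearest slot after each anchor within the window is taken (one slot per
# anchor occurrence); with all_in_window = TRUE (negative rules) every slot in
# the window is selected.
match_rule_slots <- function(sent, rule, slots, lexicon, all_in_window = FALSE) {
  m <- gregexpr(paste0("(?i)", rule$anchor), sent, perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  len <- attr(m, "match.length")
  sel <- integer(0)
  for (k in seq_along(m)) {
    a_start <- m[k]
    a_end <- m[k] + len[k] - 1L
    if (rule$position == "before") {
      cand <- which(slots$start > a_end)
      gaps <- vapply(cand, function(i) gap_tokens(sent, a_end + 1L, slots$start[i] - 1L), integer(1))
      cand <- cand[gaps <= rule$window]
      if (!all_in_window && length(cand) > 1L) cand <- cand[which.min(slots$start[cand])]
    } else {
      cand <- which(slots$end < a_start)
      gaps <- vapply(cand, function(i) gap_tokens(sent, slots$end[i] + 1L, a_start - 1L), integer(1))
      cand <- cand[gaps <= rule$window]
      if (!all_in_window && length(cand) > 1L) cand <- cand[which.max(slots$end[cand])]
    }
    if (!is.na(rule$after_req)) {
      ok <- vapply(cand, function(i) {
        rest <- substr(sent, slots$end[i] + 1L, nchar(sent))
        grepl(paste0("(?i)^\\s+(?:", rule$after_req, ")\\b"), rest, perl = TRUE)
      }, logical(1))
      cand <- cand[ok]
    }
    if (!is.na(rule$slot_canon)) {
      ok <- canonical_key(slots$surface[cand]) == rule$slot_canon
      cand <- cand[ok]
    }
    sel <- union(sel, cand)
  }
  sel
}

#' Extract design mentions from every record of a corpus
#'
#' @param corpus a corpus tibble ([new_corpus()]).
#' @param rules a [load_rules()] tibble.
#' @param lexicon a [load_lexicon()] object.
#' @param scan_titles also scan titles (off by default: designs are extracted
#'   from abstract text).
#' @return mention tibble with a `pmid` column prepended.
#' @export
extract_mentions <- function(corpus, rules, lexicon, scan_titles = FALSE) {
  res <- lapply(seq_len(nrow(corpus)), function(i) {
    txt <- corpus$abstract_text[i]
    if (scan_titles && !is.na(corpus$title[i]) && nzchar(corpus$title[i])) {
      txt <- paste0(corpus$title[i], if (grepl("[.!?]$", corpus$title[i])) " " else ". ", txt)
    }
    m <- apply_rules(txt, rules, lexicon)
    if (nrow(m) == 0L) return(NULL)
    tibble::tibble(pmid = corpus$pmid[i], m)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) {
    return(tibble::tibble(pmid = character(0), surface = character(0),
                          start = integer(0), end = integer(0),
                          rule_id = character(0), term = character(0),
                          canonical_design = character(0), sentence_index = integer(0)))
  }
  do.call(rbind, res)
}
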