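# Canonical spelling map applied token-wise: American -iz- forms unify to
# British -is- forms (the dictionary stores British spellings), and closed
# compounds open up so hyphen/space/closed variants share one canonical form.
.closed_compounds <- c(
  "nonrandomised" = "non randomised",
  "nonrandomized" = "non randomised",
  "noncontrolled" = "non controlled",
  "nonblinded"    = "non blinded",
  "noninferiority" = "non inferiority",
  "metaanalysis"  = "meta analysis",
  "metaanalyses"  = "meta analyses",
  "metaanalytic"  = "meta analytic",
  "followup"      = "follow up",
  "blinded"       = "blind"
)

# head nouns: generic tokens stripped from the end of a canonical design
# phrase before factoring into lower-level design + attributes
.head_nouns <- c("study", "studies", "design", "designs", "trial", "trials",
                 "review", "reviews")

# tokens ignored when measuring the length of a design phrase for
# representative selection ("cohort study" must lose to "prospective cohort")
.length_stopwords <- c("study", "studies", "design", "designs", "of", "a")

#' Canonicalize a study-design surface string
#'
#' Lowercases, unifies hyphen/solidus to spaces, opens closed compounds
#' (`nonrandomised` -> `non randomised`), unifies American `-iz-` spellings to
#' British `-is-`, and re-hyphenates the `meta-` family (`meta analysis` ->
#' `meta-analysis`). The function is idempotent and deterministic.
#'
#' @param x character vector of surface strings.
#' @return canonical strings.
#' @examples
#' canonicalize("Randomized Controlled Trial") # "randomised controlled trial"
#' canonicalize("meta analytic review")        # "meta-analytic review"
#' @export
canonicalize <- function(x) {
  vapply(x, function(s) {
    s <- tolower(trimws(s))
    s <- gsub("[/_‐‑‒–—―-]+", " ", s)
    s <- gsub("\\s+", " ", s)
    toks <- split_tokens(s)
    if (length(toks) == 0L) return("")
    toks <- unlist(lapply(toks, function(t) {
      if (t %in% names(.closed_compounds)) return(split_tokens(.closed_compounds[[t]]))
      if (nchar(t) >= 6L) t <- sub("iz(e|ed|ation|ations|ing)$", "is\\1", t)
      t
    }))
    s <- paste(toks, collapse = " ")
    s <- gsub("\\bmeta (analys[ei]s|analytic|regression|synthesis)\\b", "meta-\\1", s)
    s
  }, character(1), USE.NAMES = FALSE)
}

# canonical key used for dictionary lookup and relatedness: canonical form
# with the head noun singularized, so "randomised controlled trials" and
# "randomized controlled trial" collide
.singular_heads <- c(trials = "trial", studies = "study", reviews = "review",
                     surveys = "survey", analyses = "analysis",
                     "meta-analyses" = "meta-analysis", reports = "report",
                     cohorts = "cohort", experiments = "experiment")

canonical_key <- function(x) {
  vapply(canonicalize(x), function(s) {
    toks <- split_tokens(s)
    if (length(toks) == 0L) return("")
    last <- toks[length(toks)]
    if (last %in% names(.singular_heads)) toks[length(toks)] <- .singular_heads[[last]]
    paste(toks, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

# phrase length used by select_representative: characters of the canonical
# string after dropping generic stopword tokens
design_phrase_length <- function(x) {
  vapply(canonicalize(x), function(s) {
    toks <- split_tokens(s)
    toks <- toks[!toks %in% .length_stopwords]
    nchar(paste(toks, collapse = " "))
  }, integer(1), USE.NAMES = FALSE)
}

#' Select the representative design mention for one abstract
#'
#' When an abstract carries more than one design mention, the lengthiest is
#' kept on the assumption that the longer phrase is the more informative one
#' (e.g. "randomised double blinded controlled trial" beats "randomised
#' controlled trial"). Length is measured in characters of the canonical
#' phrase after dropping generic tokens ("study", "design", "of", "a"), so
#' "prospective cohort" beats "cohort study". Ties break to the earliest
#' character offset, making the choice order-invariant.
#'
#' @param mentions a mention tibble (from [apply_rules()]) with at least
#'   `surface` and `start` columns.
#' @return the selected mention row.
#' @export
select_representative <- function(mentions) {
  if (is.null(mentions) || nrow(mentions) == 0L) {
    stop("no design extracted: cannot select a representative from zero mentions",
         call. = FALSE)
  }
  len <- design_phrase_length(mentions$surface)
  best <- which(len == max(len))
  if (length(best) > 1L) best <- best[order(mentions$start[best])][1]
  mentions[best, , drop = FALSE]
}

#' Factor a canonical design phrase into lower-level design plus attributes
#'
#' Strips trailing generic head nouns (study/trial/review/design and their
#' plurals), then searches the classification schema for the longest
#' lower-level design whose tokens appear (in order) in the phrase, such that
#' every remaining token is consumed by attribute vocabulary of that design's
#' high-level node. If no factoring consumes all tokens the phrase is
#' ambiguous and routes to the miscellaneous node (empty lower level, no
#' attributes).
#'
#' @param canonical a canonical design phrase (see [canonicalize()]).
#' @param lexicon a [load_lexicon()] object.
#' @return list with `lower_level` (string, `""` when miscellaneous) and
#'   `attributes` (character vector of canonical attribute names).
#' @examples
#' lex <- load_lexicon()
#' split_design_attributes("prospective cohort", lex)
#' split_design_attributes("randomised double blinded controlled trial", lex)
#' @export
split_design_attributes <- function(canonical, lexicon) {
  stopifnot(is.character(canonical), length(canonical) == 1L)
  toks <- split_tokens(canonical_key(canonical))
  while (length(toks) > 0L && toks[length(toks)] %in% .head_nouns) {
    toks <- toks[-length(toks)]
  }
  if (length(toks) == 0L) return(list(lower_level = "", attributes = character(0)))

  lowers <- lexicon$schema$match_lowers # named chr: label -> node
  best <- NULL
  for (lab in names(lowers)) {
    lab_toks <- split_tokens(lab)
    cons <- match_subsequence(toks, lab_toks)
    if (is.null(cons)) next
    leftover <- toks[-cons]
    attrs <- consume_attributes(leftover, lowers[[lab]], lexicon)
    if (is.null(attrs)) next
    if (is.null(best) || nchar(lab) > nchar(best$lower_level)) {
      best <- list(lower_level = lab, attributes = attrs)
    }
  }
  if (is.null(best)) list(lower_level = "", attributes = character(0)) else best
}

# indices in `toks` consumed by matching `lab_toks` as an ordered (possibly
# non-contiguous) subsequence, or NULL if no match
match_subsequence <- function(toks, lab_toks) {
  idx <- integer(0)
  j <- 1L
  for (i in seq_along(toks)) {
    if (j > length(lab_toks)) break
    if (toks[i] == lab_toks[j]) {
      idx <- c(idx, i)
      j <- j + 1L
    }
  }
  if (j <= length(lab_toks)) NULL else idx
}

# greedily segment leftover tokens into attribute phrases allowed for `node`;
# returns canonical attribute names, or NULL if any token is unconsumable
consume_attributes <- function(leftover, node, lexicon) {
  if (length(leftover) == 0L) return(character(0))
  attrs <- lexicon$attributes[lexicon$attributes$node == node, , drop = FALSE]
  if (nrow(attrs) == 0L) return(NULL)
  # all matchable forms, longest first
  forms <- do.call(rbind, lapply(seq_len(nrow(attrs)), function(i) {
    vs <- unique(c(attrs$attribute[i], attrs$variants[[i]]))
    data.frame(form = vs, name = attrs$attribute[i], stringsAsFactors = FALSE)
  }))
  forms$ntok <- vapply(forms$form, function(f) length(split_tokens(f)), integer(1))
  forms <- forms[order(-forms$ntok), , drop = FALSE]
  out <- character(0)
  i <- 1L
  while (i <= length(leftover)) {
    hit <- FALSE
    for (k in seq_len(nrow(forms))) {
      ft <- split_tokens(forms$form[k])
      n <- length(ft)
      if (i + n - 1L <= length(leftover) && all(leftover[i:(i + n - 1L)] == ft)) {
        out <- c(out, forms$name[k])
        i <- i + n
        hit <- TRUE
        break
      }
    }
    if (!hit) return(NULL)
  }
  unique(out)
}

#' Classify a lower-level design into its high-level node
#'
#' @param lower_level canonical lower-level design label (`""` for ambiguous).
#' @param lexicon a [load_lexicon()] object.
#' @return one of `"observational"`, `"trial"`, `"review"`, `"meta-analysis"`,
#'   `"miscellaneous"`.
#' @export
classify_high_level <- function(lower_level, lexicon) {
  vapply(lower_level, function(l) {
    if (!nzchar(l)) return("miscellaneous")
    node <- lexicon$schema$match_lowers[[l]]
    if (is.null(node)) "miscellaneous" else node
  }, character(1), USE.NAMES = FALSE)
}

#' Map a standardized design onto the hierarchy of scientific evidence
#'
#' Designs on the miscellaneous node, and lower-level designs that no tier
#' admits, receive the unmappable label.
#'
#' @param lower_level canonical lower-level design label.
#' @param high_level high-level node for that design.
#' @param lexicon a [load_lexicon()] object.
#' @return tier name, or the hierarchy's unmappable label.
#' @export
map_to_hierarchy <- function(lower_level, high_level, lexicon) {
  hy <- lexicon$hierarchy
  mapply(function(l, h) {
    if (h == "miscellaneous" || !nzchar(l)) return(hy$unmappable_label)
    for (tier in hy$tiers) {
      if (l %in% tier$members) return(tier$name)
    }
    hy$unmappable_label
  }, lower_level, high_level, USE.NAMES = FALSE)
}

#' Standardize extracted mentions to one design per abstract
#'
#' Implements abstract-level unification: for each abstract with at least one
#' mention, the lengthiest mention becomes the representative design, which is
#' canonicalized, factored into lower-level design plus attributes, and
#' classified into a high-level node. All mentions are retained in a
#' list-column for audit so no information is lost by unification.
#'
#' @param mentions mention tibble from [extract_mentions()] (must carry
#'   `pmid`).
#' @param lexicon a [load_lexicon()] object.
#' @return tibble with one row per abstract: `pmid`, `representative_surface`,
#'   `canonical`, `lower_level`, `high_level`, `attributes` (list-column),
#'   `n_mentions`, `all_mentions` (list-column).
#' @export
standardize_designs <- function(mentions, lexicon) {
  if (nrow(mentions) == 0L) {
    return(tibble::tibble(pmid = character(0), representative_surface = character(0),
                          canonical = character(0), lower_level = character(0),
                          high_level = character(0), attributes = list(),
                          n_mentions = integer(0), all_mentions = list()))
  }
  rows <- lapply(split(mentions, mentions$pmid), function(m) {
    rep <- select_representative(m)
    canon <- canonicalize(rep$surface)
    fac <- split_design_attributes(canon, lexicon)
    high <- classify_high_level(fac$lower_level, lexicon)
    attrs <- if (high == "miscellaneous") character(0) else fac$attributes
    tibble::tibble(pmid = m$pmid[1], representative_surface = rep$surface,
                   canonical = canon, lower_level = fac$lower_level,
                   high_level = high, attributes = list(attrs),
                   n_mentions = nrow(m), all_mentions = list(m))
  })
  out <- do.call(rbind, rows)
  out[order(out$pmid), , drop = FALSE]
}

#' Assign evidence-hierarchy tiers to standardized designs
#'
#' @param designs output of [standardize_designs()].
#' @param lexicon a [load_lexicon()] object.
#' @return `designs` with an added `tier` column (one assignment per abstract).
#' @export
assign_hierarchy <- function(designs, lexicon) {
  designs$tier <- map_to_hierarchy(designs$lower_level, designs$high_level, lexicon)
  designs
}
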