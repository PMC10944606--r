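# spelling twins: British -is- <-> American -iz- on sufficiently long tokens
spelling_twins <- function(tok) {
  out <- tok
  if (nchar(tok) >= 6L) {
    if (grepl("is(e|ed|ation|ations|ing)$", tok)) {
      out <- c(out, sub("is(e|ed|ation|ations|ing)$", "iz\\1", tok))
    } else if (grepl("iz(e|ed|ation|ations|ing)$", tok)) {
      out <- c(out, sub("iz(e|ed|ation|ations|ing)$", "is\\1", tok))
    }
  }
  unique(out)
}

# singular <-> plural pairs for design head nouns
.plural_pairs <- c(trial = "trials", study = "studies", review = "reviews",
                   survey = "surveys", analysis = "analyses", report = "reports",
                   cohort = "cohorts", experiment = "experiments")

plural_twins <- function(tok) {
  if (tok %in% names(.plural_pairs)) return(c(tok, .plural_pairs[[tok]]))
  hit <- names(.plural_pairs)[match(tok, .plural_pairs)]
  if (!is.na(hit)) return(c(hit, tok))
  tok
}

# closure of one surface string under spelling, hyphen<->space and head-noun
# plural alternation
variant_closure <- function(s) {
  toks <- strsplit(tolower(trimws(s)), "[ -]+")[[1]]
  if (length(toks) == 0L) return(character(0))
  alts <- lapply(toks, spelling_twins)
  alts[[length(alts)]] <- unique(unlist(lapply(alts[[length(alts)]], plural_twins)))
  combos <- expand.grid(alts, stringsAsFactors = FALSE)
  phrases <- apply(combos, 1L, function(r) as.character(r), simplify = FALSE)
  out <- character(0)
  for (ph in phrases) {
    if (length(ph) == 1L) {
      out <- c(out, ph)
    } else {
      seps <- expand.grid(rep(list(c(" ", "-")), length(ph) - 1L), stringsAsFactors = FALSE)
      for (k in seq_len(nrow(seps))) {
        parts <- character(0)
        for (i in seq_along(ph)) {
          parts <- c(parts, ph[i], if (i < length(ph)) as.character(seps[k, i]))
        }
        out <- c(out, paste(parts, collapse = ""))
      }
    }
  }
  unique(out)
}

#' Expand a lexicon term to its matchable surface variants
#'
#' Returns the closure of a term (plus any manually listed variants) under
#' three alternations: British/American spelling (`randomised` /
#' `randomized`), hyphen/space between tokens (`case-control` /
#' `case control` -- closed forms like `crosssectional` are deliberately not
#' generated), and singular/plural of the head noun (`trial` / `trials`).
#' The expansion is idempotent: expanding any returned string yields the same
#' set.
#'
#' @param term the canonical (lowercase) term string.
#' @param variants optional manual extra variants (e.g. closed compounds such
#'   as `"nonrandomised trial"`).
#' @return character vector of surface variants (includes `term` itself).
#' @examples
#' expand_variants("randomised controlled trial")
#' expand_variants("meta-analysis")
#' @export
expand_variants <- function(term, variants = character(0)) {
  seeds <- unique(c(term, variants))
  sort(unique(unlist(lapply(seeds, variant_closure))))
}

default_lexicon_path <- function() {
  system.file("extdata", "design_lexicon.yaml", package = "designminer", mustWork = TRUE)
}

#' Load the study-design lexicon, classification schema and hierarchy
#'
#' Reads a single structured config file housing (i) the design-term
#' dictionary (the shipped default has exactly 134 terms), (ii) the attribute
#' vocabulary per high-level node, (iii) the classification schema mapping
#' lower-level designs to the five high-level nodes, and (iv) the ordered
#' evidence-hierarchy table. The config is user-replaceable; validation is
#' strict: duplicate terms, dangling canonical designs or dangling hierarchy
#' members are load errors.
#'
#' @param path config file (YAML); defaults to the shipped lexicon.
#' @return an object of class `design_lexicon`: list with elements `terms`
#'   (tibble: `term`, `canonical_design`, `variants` list-column),
#'   `attributes` (tibble: `attribute`, `node`, `variants`), `schema` (nodes,
#'   `lower_levels` per node, flat `match_lowers` map used for factoring),
#'   `hierarchy` (ordered tiers + unmappable label), and compiled matching
#'   tables used by the rule engine.
#' @export
load_lexicon <- function(path = default_lexicon_path()) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg) || is.null(cfg$terms) || length(cfg$terms) == 0L) {
    stop("lexicon config is empty or has no terms", call. = FALSE)
  }
  nodes <- unlist(cfg$nodes)
  lower_levels <- lapply(cfg$lower_levels, function(x) as.character(unlist(x)))
  qualifier_only <- as.character(unlist(cfg$qualifier_only))
  # flat label -> node map used for design/attribute factoring; qualifier-only
  # sub-type labels are listed in the schema but never matched bare
  match_lowers <- list()
  for (node in names(lower_levels)) {
    for (lab in lower_levels[[node]]) {
      if (lab %in% qualifier_only) next
      if (!is.null(match_lowers[[lab]])) {
        stop(sprintf("lower-level design '%s' mapped to more than one node", lab),
             call. = FALSE)
      }
      match_lowers[[lab]] <- node
    }
  }

  attr_rows <- list()
  for (node in names(cfg$attributes)) {
    for (a in cfg$attributes[[node]]) {
      attr_rows[[length(attr_rows) + 1L]] <- tibble::tibble(
        attribute = a$name, node = node,
        variants = list(as.character(unlist(a$variants))))
    }
  }
  attributes <- if (length(attr_rows)) do.call(rbind, attr_rows) else {
    tibble::tibble(attribute = character(0), node = character(0), variants = list())
  }
  bad <- vapply(c(attributes$attribute, unlist(attributes$variants)),
                function(a) is.na(a) || !nzchar(trimws(a)) || a != tolower(trimws(a)),
                logical(1))
  if (any(bad)) stop("attributes must be non-empty, lowercase and trimmed", call. = FALSE)

  terms <- do.call(rbind, lapply(cfg$terms, function(t) {
    tibble::tibble(term = t$term,
                   canonical_design = t$canonical,
                   variants = list(as.character(unlist(t$variants))))
  }))
  chk <- c(terms$term, unlist(terms$variants))
  if (any(is.na(chk) | !nzchar(trimws(chk)) | chk != tolower(trimws(chk)))) {
    stop("lexicon terms and variants must be non-empty, lowercase and trimmed",
         call. = FALSE)
  }
  if (anyDuplicated(terms$term)) {
    stop(sprintf("duplicate lexicon term(s): %s",
                 paste(unique(terms$term[duplicated(terms$term)]), collapse = ", ")),
         call. = FALSE)
  }
  known <- c(names(match_lowers), qualifier_only, "miscellaneous")
  dangling <- setdiff(unique(terms$canonical_design), known)
  if (length(dangling) > 0L) {
    stop(sprintf("canonical_design not in classification schema: %s",
                 paste(dangling, collapse = ", ")), call. = FALSE)
  }

  tiers <- lapply(cfg$hierarchy$tiers, function(t) {
    list(name = t$name, members = as.character(unlist(t$members)))
  })
  tier_members <- unlist(lapply(tiers, `[[`, "members"))
  if (anyDuplicated(tier_members)) {
    stop("a design may belong to at most one hierarchy tier", call. = FALSE)
  }
  dangling_tier <- setdiff(tier_members, c(names(match_lowers), qualifier_only))
  if (length(dangling_tier) > 0L) {
    stop(sprintf("hierarchy members not in classification schema: %s",
                 paste(dangling_tier, collapse = ", ")), call. = FALSE)
  }

  lex <- list(
    terms = terms,
    attributes = attributes,
    schema = list(nodes = nodes, lower_levels = lower_levels,
                  qualifier_only = qualifier_only,
                  dual_role = as.character(unlist(cfg$dual_role)),
                  match_lowers = match_lowers),
    hierarchy = list(unmappable_label = cfg$hierarchy$unmappable_label,
                     tiers = tiers),
    version = cfg$version
  )
  lex$matcher <- build_term_matcher(lex)
  class(lex) <- "design_lexicon"
  lex
}

# compile the dictionary into (i) one case-insensitive alternation regex with
# longer terms tried first (leftmost-longest matching) and (ii) a canonical
# key -> term-row lookup used to resolve matched surfaces
build_term_matcher <- function(lex) {
  pats <- character(0)
  keys <- character(0)
  rows <- integer(0)
  for (i in seq_len(nrow(lex$terms))) {
    vars <- expand_variants(lex$terms$term[i], lex$terms$variants[[i]])
    # regex skeletons: space-joined forms with [ \s-]+ separators cover the
    # hyphen/space alternation without enumerating it
    skel <- unique(gsub("-", " ", vars))
    skel <- unique(gsub("\\bmeta (analys[ei]s)\\b", "meta \\1", skel))
    for (s in skel) {
      toks <- split_tokens(s)
      pat <- paste(vapply(toks, function(t) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", t),
                          character(1)),
                   collapse = "[\\s-]+")
      pats <- c(pats, pat)
    }
    ks <- unique(canonical_key(vars))
    keys <- c(keys, ks)
    rows <- c(rows, rep(i, length(ks)))
  }
  ord <- order(-nchar(pats))
  lookup <- rows
  names(lookup) <- keys
  if (anyDuplicated(keys)) {
    d <- unique(keys[duplicated(keys)])
    stop(sprintf("lexicon terms collide after normalization: %s",
                 paste(d, collapse = ", ")), call. = FALSE)
  }
  list(regex = paste0("(?i)\\b(?:", paste(unique(pats[ord]), collapse = "|"), ")\\b"),
       lookup = lookup)
}

# resolve a matched surface to its lexicon term row index (NA if unknown)
lookup_term <- function(surface, lexicon) {
  idx <- lexicon$matcher$lookup[canonical_key(surface)]
  unname(idx)
}

#' Validate a loaded lexicon and summarize its contracts
#'
#' @param lexicon a [load_lexicon()] object.
#' @return list with `n_terms`, `n_attributes`, `nodes`, `n_tiers`, plus any
#'   warnings about dual-role labels; printed as a short report.
#' @export
validate_lexicon <- function(lexicon) {
  stopifnot(inherits(lexicon, "design_lexicon"))
  res <- list(
    n_terms = nrow(lexicon$terms),
    n_attributes = nrow(lexicon$attributes),
    nodes = lexicon$schema$nodes,
    n_tiers = length(lexicon$hierarchy$tiers),
    dual_role = lexicon$schema$dual_role
  )
  class(res) <- "lexicon_validation"
  res
}

#' @export
print.lexicon_validation <- function(x, ...) {
  cat(sprintf("design lexicon: %d terms, %d attributes, nodes: %s; %d hierarchy tiers\n",
              x$n_terms, x$n_attributes, paste(x$nodes, collapse = ", "), x$n_tiers))
  if (length(x$dual_role)) {
    cat("dual-role labels (design and attribute):", paste(x$dual_role, collapse = ", "), "\n")
  }
  invisible(x)
}
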