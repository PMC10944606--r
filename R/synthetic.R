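# default design frequency weights: the observed lower-level design counts in
# the source discipline (top-20 table plus meta-analyses), so synthetic
# corpora stress the same head-heavy distribution
.default_design_weights <- c(
  "systematic" = 1432, "randomised controlled" = 1136, "case report" = 806,
  "cross sectional" = 634, "cohort" = 626, "randomised" = 611,
  "scoping" = 202, "descriptive" = 157, "case control" = 123,
  "controlled" = 79, "survey" = 71, "cluster randomised controlled" = 60,
  "quasi experimental" = 52, "cluster randomised" = 47, "meta-analytic" = 31,
  "non randomised controlled" = 23, "systematic scoping" = 21,
  "cross sectional descriptive" = 18, "ecological" = 13, "non randomised" = 12,
  "meta-analysis" = 190
)

# default attribute weights: observed attribute frequencies among trial and
# observational designs
.default_attribute_weights <- c(
  "double blind" = 149, "pilot" = 89, "phase 2" = 55, "single blind" = 49,
  "phase 3" = 49, "phase 1" = 30, "cost effectiveness" = 25,
  "feasibility" = 17, "two arm" = 16, "superiority" = 11,
  "non inferiority" = 11, "efficacy" = 8, "equivalence" = 3, "phase 4" = 3,
  "triple blind" = 1,
  "retrospective" = 974, "comparison" = 712, "prospective" = 633,
  "qualitative" = 170, "case series" = 154, "population based" = 76,
  "follow up" = 75, "exploratory" = 64, "quantitative" = 48, "nested" = 14,
  "survival" = 13, "time series" = 7, "interrupted time series" = 7,
  "natural experiment" = 6, "serial" = 4, "propensity matched" = 1
)

#' Configuration for the synthetic abstract generator
#'
#' Defaults emulate the study conditions of the source discipline: design
#' frequencies proportional to the observed lower-level design counts,
#' attribute frequencies proportional to the observed attribute counts,
#' publication years spanning 1963-2023, roughly 60% of abstracts stating no
#' design (only ~40% of real abstracts had an extractable design), and modest
#' rates of duplicate mentions and adversarial prior-study references.
#'
#' @param n_abstracts number of abstracts to generate.
#' @param seed integer seed; generation is reproducible given the seed.
#' @param p_no_design probability an abstract states no design.
#' @param p_duplicate_mention probability a stated design is mentioned twice
#'   (once fully, once partially).
#' @param p_adversarial probability of inserting a prior-study negative
#'   context ("follow up of a <design>").
#' @param p_attribute probability a stated design carries an attribute-laden
#'   surface form when the dictionary has one (default 0.475: about half of
#'   real designs carried attributes).
#' @param design_distribution named non-negative weights over lower-level
#'   designs; names must exist in the classification schema.
#' @param attribute_distribution named non-negative weights over attributes.
#' @param year_range inclusive publication-year span.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_abstracts = 500L, seed = 1L,
                             p_no_design = 0.6, p_duplicate_mention = 0.25,
                             p_adversarial = 0.15, p_attribute = 0.475,
                             design_distribution = NULL,
                             attribute_distribution = NULL,
                             year_range = c(1963L, 2023L)) {
  probs <- c(p_no_design = p_no_design, p_duplicate_mention = p_duplicate_mention,
             p_adversarial = p_adversarial, p_attribute = p_attribute)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  dd <- design_distribution %||% .default_design_weights
  ad <- attribute_distribution %||% .default_attribute_weights
  if (any(dd < 0) || all(dd == 0)) stop("design weights must be non-negative, not all zero", call. = FALSE)
  if (any(ad < 0) || all(ad == 0)) stop("attribute weights must be non-negative, not all zero", call. = FALSE)
  stopifnot(length(year_range) == 2L, year_range[1] <= year_range[2], year_range[1] >= 1900L)
  structure(list(n_abstracts = as.integer(n_abstracts), seed = as.integer(seed),
                 p_no_design = p_no_design, p_duplicate_mention = p_duplicate_mention,
                 p_adversarial = p_adversarial, p_attribute = p_attribute,
                 design_distribution = dd, attribute_distribution = ad,
                 year_range = as.integer(year_range)),
            class = "generator_config")
}

.filler_sentences <- c(
  "Participants were recruited from three correctional facilities between 2012 and 2016.",
  "Data were collected through structured interviews administered at reception.",
  "Outcomes included self reported substance use and access to primary care.",
  "Rates of infection were higher among people on remand than among sentenced groups.",
  "Attrition at twelve months was below ten percent across all sites.",
  "Findings highlight substantial unmet health needs in custodial settings.",
  "Services were delivered by visiting primary care teams under standard conditions.",
  "Ethical approval was granted by the relevant institutional committees."
)

# positive templates; each phrasing is an anchor the default rule set declares
.design_templates <- c(
  "We conducted a %s of hepatitis C treatment uptake in two prisons.",
  "This was a %s involving 240 adult participants.",
  "We report a %s of smoking cessation support for people leaving custody.",
  "A %s was conducted across four correctional facilities.",
  "We used a %s to examine vaccination coverage on reception."
)
.duplicate_template <- "The %s design was used to address these questions."
.adversarial_template <- "We conducted a six year follow up of a %s."

# head nouns that design phrases already end in; anything else gets " study"
.self_headed <- c("trial", "trials", "review", "reviews", "survey", "surveys",
                  "report", "reports", "analysis", "analyses", "meta-analysis",
                  "meta-analyses", "experiment", "experiments", "randomisation",
                  "investigation", "evaluation", "audit", "surveillance",
                  "series", "study", "studies", "approach", "intervention",
                  "synthesis", "regression", "randomization")

with_head <- function(surface) {
  toks <- split_tokens(canonicalize(surface))
  if (length(toks) > 0L && toks[length(toks)] %in% .self_headed) surface
  else paste(surface, "study")
}

# factor every lexicon term once: term -> (lower level, attributes, key)
factor_terms <- function(lexicon) {
  keys <- canonical_key(lexicon$terms$term)
  fac <- lapply(keys, split_design_attributes, lexicon = lexicon)
  tibble::tibble(term = lexicon$terms$term, key = keys,
                 lower = vapply(fac, `[[`, character(1), "lower_level"),
                 n_attrs = vapply(fac, function(f) length(f$attributes), integer(1)),
                 first_attr = vapply(fac, function(f) {
                   if (length(f$attributes)) f$attributes[1] else NA_character_
                 }, character(1)))
}

#' Generate a gold-annotated synthetic abstract corpus
#'
#' Abstracts are template-filled English sentences around anchor phrasings the
#' default rule set declares, with design surfaces drawn from the lexicon in a
#' random spelling/hyphenation variant. Injected phenomena: duplicate partial
#' mentions of one design ("prospective cohort" ... "cohort"), adversarial
#' prior-study references ("follow up of a <design>") that a correct extractor
#' must suppress, and design-free abstracts whose only design terms (if any)
#' sit inside adversarial contexts. The gold annotation is exactly the set of
#' designs injected through positive templates.
#'
#' @param config a [generator_config()].
#' @param lexicon a [load_lexicon()] object.
#' @return list with `corpus` (a [new_corpus()] tibble), `gold` (tibble:
#'   `pmid`, `gold_designs` list-column), and `bookkeeping` (tibble recording
#'   which phenomena were injected per abstract).
#' @export
generate_corpus <- function(config = generator_config(), lexicon = load_lexicon()) {
  stopifnot(inherits(config, "generator_config"))
  ft <- factor_terms(lexicon)
  unknown <- setdiff(names(config$design_distribution),
                     c(names(lexicon$schema$match_lowers), "miscellaneous"))
  if (length(unknown) > 0L) {
    stop(sprintf("design weights reference unknown designs: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  dd <- config$design_distribution
  dd <- dd[names(dd) %in% ft$lower] # only lowers the dictionary can surface
  set.seed(config$seed)
  n <- config$n_abstracts
  rec_rows <- vector("list", n)
  gold_rows <- vector("list", n)
  bk_rows <- vector("list", n)
  for (i in seq_len(n)) {
    pmid <- sprintf("SYN%05d", i)
    year <- sample(seq(config$year_range[1], config$year_range[2]), 1L)
    no_design <- runif(1) < config$p_no_design
    adversarial <- runif(1) < config$p_adversarial
    sents <- sample(.filler_sentences, 3L)
    design_key <- character(0)
    term <- NA_character_; duplicate <- FALSE; adv_design <- NA_character_
    if (!no_design) {
      lower <- sample(names(dd), 1L, prob = dd)
      cand <- ft[ft$lower == lower, , drop = FALSE]
      bare <- cand[cand$n_attrs == 0L, , drop = FALSE]
      bare <- bare[which.min(nchar(bare$key)), , drop = FALSE]
      pick <- bare
      if (runif(1) < config$p_attribute) {
        attributed <- cand[cand$n_attrs > 0L, , drop = FALSE]
        if (nrow(attributed) > 0L) {
          w <- config$attribute_distribution[attributed$first_attr]
          w[is.na(w)] <- 1
          pick <- attributed[sample(nrow(attributed), 1L, prob = w), , drop = FALSE]
        }
      }
      term <- pick$term
      design_key <- pick$key
      vars <- expand_variants(term, variants = lexicon$terms$variants[[
        match(term, lexicon$terms$term)]])
      # keep grammatical singular-head variants only ("a case reports" is not)
      head_of <- function(x) {
        t <- split_tokens(canonicalize(x))
        t[length(t)]
      }
      vars <- vars[vapply(vars, head_of, character(1)) == head_of(term)]
      surface <- sample(vars, 1L)
      tmpl <- sample(.design_templates, 1L)
      design_sentence <- sprintf(tmpl, with_head(surface))
      sents <- append(sents, design_sentence, after = 1L)
      duplicate <- runif(1) < config$p_duplicate_mention
      if (duplicate) {
        partial <- partial_term(pick, ft)
        sents <- append(sents, sprintf(.duplicate_template, partial), after = 3L)
      }
    }
    if (adversarial) {
      pool <- ft$key[ft$lower != "" & !vapply(ft$key, function(k) {
        length(design_key) > 0L && related_designs(k, design_key)
      }, logical(1))]
      adv_design <- sample(pool, 1L)
      sents <- c(sents, sprintf(.adversarial_template, with_head(adv_design)))
    }
    rec_rows[[i]] <- tibble::tibble(
      pmid = pmid,
      title = "Health and justice outcomes among incarcerated adults: a multi site investigation",
      abstract_text = paste(sents, collapse = " "),
      pub_year = year, pub_types = list("Journal Article"), language = "eng")
    gold_rows[[i]] <- tibble::tibble(pmid = pmid, gold_designs = list(design_key))
    bk_rows[[i]] <- tibble::tibble(pmid = pmid, design = if (length(design_key)) design_key else NA_character_,
                                   term = term, duplicate = duplicate,
                                   adversarial = adversarial, adversarial_design = adv_design,
                                   pub_year = year)
  }
  list(corpus = new_corpus(do.call(rbind, rec_rows),
                           source_description = sprintf("synthetic(seed=%d,n=%d)", config$seed, n)),
       gold = do.call(rbind, gold_rows),
       bookkeeping = do.call(rbind, bk_rows),
       config = config)
}

# a shorter lexicon term related to the picked one (its partial mention);
# falls back to repeating the same term
partial_term <- function(pick, ft) {
  cand <- ft[ft$key != pick$key & nchar(ft$key) < nchar(pick$key), , drop = FALSE]
  rel <- vapply(cand$key, function(k) related_designs(k, pick$key), logical(1))
  if (any(rel)) {
    ks <- cand$key[rel]
    ks[which.max(nchar(ks))]
  } else {
    pick$key
  }
}

#' Corrupt gold annotations into imperfect predictions with exact bookkeeping
#'
#' Drops each gold design with probability `fn_rate` and injects an unrelated
#' design with probability `fp_rate` per abstract, returning both the
#' predictions and the exact TP/FP/FN counts implied by its own coin flips --
#' the oracle for testing [evaluate_corpus()].
#'
#' @param gold gold tibble from [generate_corpus()].
#' @param fp_rate,fn_rate corruption rates in `[0, 1]`.
#' @param seed integer seed.
#' @param lexicon a [load_lexicon()] object (pool for injected designs).
#' @return list with `predictions` (tibble: `pmid`, `canonical`) and
#'   `expected` (list tp/fp/fn).
#' @export
corrupt_predictions <- function(gold, fp_rate, fn_rate, seed = 1L,
                                lexicon = load_lexicon()) {
  stopifnot(fp_rate >= 0, fp_rate <= 1, fn_rate >= 0, fn_rate <= 1)
  ft <- factor_terms(lexicon)
  pool <- unique(ft$key)
  set.seed(seed)
  tp <- 0L; fp <- 0L; fn <- 0L
  rows <- list()
  for (i in seq_len(nrow(gold))) {
    pm <- gold$pmid[i]
    g <- gold$gold_designs[[i]]
    kept <- character(0)
    for (d in g) {
      if (runif(1) < fn_rate) fn <- fn + 1L
      else { tp <- tp + 1L; kept <- c(kept, d) }
    }
    if (runif(1) < fp_rate) {
      cand <- pool[!vapply(pool, function(k) {
        any(vapply(g, function(d) related_designs(k, d), logical(1)))
      }, logical(1))]
      inj <- sample(cand, 1L)
      fp <- fp + 1L
      kept <- c(kept, inj)
    }
    if (length(kept) > 0L) {
      rows[[length(rows) + 1L]] <- tibble::tibble(pmid = pm, canonical = kept)
    }
  }
  predictions <- if (length(rows)) do.call(rbind, rows) else {
    tibble::tibble(pmid = character(0), canonical = character(0))
  }
  list(predictions = predictions, expected = list(tp = tp, fp = fp, fn = fn))
}
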