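#' Are two canonical designs related?
#'
#' Relatedness drives abstract-level scoring: a predicted design detects a
#' gold design if the two canonical phrases are equal or one is a (token-wise,
#' contiguous) sub-phrase of the other -- "cohort study" detects "prospective
#' cohort". Containment is directional-agnostic.
#'
#' @param a,b design phrases (canonicalized internally).
#' @return logical.
#' @export
related_designs <- function(a, b) {
  ka <- split_tokens(canonical_key(a))
  kb <- split_tokens(canonical_key(b))
  # generic head nouns do not count towards containment
  ka <- ka[!ka %in% .length_stopwords]
  kb <- kb[!kb %in% .length_stopwords]
  if (length(ka) == 0L || length(kb) == 0L) return(FALSE)
  tokens_contained(ka, kb) || tokens_contained(kb, ka)
}

#' Score one abstract against its gold annotation
#'
#' Abstract-level counting: each gold design is a true positive if at least
#' one related mention was extracted (detecting any of several mentions of one
#' design suffices), and a false negative if every mention of it was missed.
#' Each group of extracted designs unrelated to every gold design is one false
#' positive (mutually related predictions count once -- they are mentions of
#' one design).
#'
#' @param gold_designs character vector of canonical gold designs (possibly
#'   empty).
#' @param predicted character vector of predicted design surfaces or canonical
#'   phrases (possibly empty); a mention tibble is also accepted.
#' @return list with integer `tp`, `fp`, `fn`.
#' @export
score_abstract <- function(gold_designs, predicted) {
  if (is.data.frame(predicted)) predicted <- predicted$surface
  gold <- unique(canonical_key(gold_designs))
  gold <- gold[nzchar(gold)]
  pred <- unique(canonical_key(predicted))
  pred <- pred[nzchar(pred)]
  tp <- 0L; fn <- 0L
  for (g in gold) {
    hit <- any(vapply(pred, function(p) related_designs(g, p), logical(1)))
    if (hit) tp <- tp + 1L else fn <- fn + 1L
  }
  unrelated <- pred[!vapply(pred, function(p) {
    any(vapply(gold, function(g) related_designs(g, p), logical(1)))
  }, logical(1))]
  fp <- n_related_groups(unrelated)
  list(tp = tp, fp = fp, fn = fn)
}

# number of connected components of the relatedness graph
n_related_groups <- function(designs) {
  n <- length(designs)
  if (n == 0L) return(0L)
  comp <- seq_len(n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (related_designs(designs[i], designs[j])) {
        comp[comp == comp[j]] <- comp[i]
      }
    }
  }
  length(unique(comp))
}

#' Precision, recall and F1 from TP/FP/FN counts
#'
#' Percentages are truncated (floored) to one decimal, and F1 is the harmonic
#' mean of the truncated precision and recall, itself truncated -- the
#' convention under which the published evaluation table recomputes exactly
#' from its counts. An undefined metric (zero denominator) is `NA`
#' ("not applicable"), never 0.
#'
#' @param tp,fp,fn non-negative integer counts; `tp` may also be a list with
#'   elements `tp`, `fp`, `fn` (as returned by [score_abstract()]).
#' @return list of class `design_metrics` with `precision`, `recall`, `f1`
#'   on the 0-100 scale.
#' @examples
#' compute_metrics(72, 5, 7) # precision 93.5, recall 91.1, f1 92.2
#' @export
compute_metrics <- function(tp, fp = NULL, fn = NULL) {
  if (is.list(tp)) { fp <- tp$fp; fn <- tp$fn; tp <- tp$tp }
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) trunc1(100 * tp / (tp + fp)) else NA_real_
  recall <- if (tp + fn > 0) trunc1(100 * tp / (tp + fn)) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    trunc1(2 * precision * recall / (precision + recall))
  } else NA_real_
  structure(list(precision = precision, recall = recall, f1 = f1),
            class = "design_metrics")
}

#' @export
print.design_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "n/a" else sprintf("%.1f", v)
  cat(sprintf("precision %s | recall %s | F1 %s\n",
              fmt(x$precision), fmt(x$recall), fmt(x$f1)))
  invisible(x)
}

#' Evaluate predictions over a gold-annotated corpus
#'
#' Counts are summed over abstracts and the metrics computed from the summed
#' counts. The per-abstract report records every TP/FN decision per gold
#' design and every FP group with the triggering prediction, for error
#' analysis.
#'
#' @param gold tibble with `pmid` and `gold_designs` (list-column of canonical
#'   design vectors; empty vector = no reportable design). Must be non-empty.
#' @param predictions mention tibble with `pmid` and `surface` (or `canonical`)
#'   columns; abstracts without predictions simply have no rows.
#' @param corpus optional corpus; when given, every gold pmid must exist in it.
#' @return list with `counts` (tp/fp/fn), `metrics` ([compute_metrics()]) and
#'   `report` (tibble: pmid, design, status, matched_prediction).
#' @export
evaluate_corpus <- function(gold, predictions, corpus = NULL) {
  if (is.null(gold) || nrow(gold) == 0L) stop("gold set is empty", call. = FALSE)
  if (anyDuplicated(gold$pmid)) stop("duplicate pmid in gold set", call. = FALSE)
  if (!is.null(corpus)) {
    missing <- setdiff(gold$pmid, corpus$pmid)
    if (length(missing) > 0L) {
      stop(sprintf("gold pmid(s) absent from corpus: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  pred_col <- if ("canonical" %in% names(predictions)) "canonical" else "surface"
  tp <- 0L; fp <- 0L; fn <- 0L
  rep_rows <- list()
  for (i in seq_len(nrow(gold))) {
    pm <- gold$pmid[i]
    g <- gold$gold_designs[[i]]
    p <- predictions[[pred_col]][predictions$pmid == pm]
    s <- score_abstract(g, p)
    tp <- tp + s$tp; fp <- fp + s$fp; fn <- fn + s$fn
    pk <- unique(canonical_key(p))
    for (gd in unique(canonical_key(g))) {
      hit <- pk[vapply(pk, function(x) related_designs(gd, x), logical(1))]
      rep_rows[[length(rep_rows) + 1L]] <- tibble::tibble(
        pmid = pm, design = gd,
        status = if (length(hit)) "TP" else "FN",
        matched_prediction = if (length(hit)) hit[1] else NA_character_)
    }
    unrelated <- pk[!vapply(pk, function(x) {
      any(vapply(unique(canonical_key(g)), function(gd) related_designs(gd, x), logical(1)))
    }, logical(1))]
    if (length(unrelated) > 0L && s$fp > 0L) {
      rep_rows[[length(rep_rows) + 1L]] <- tibble::tibble(
        pmid = pm, design = unrelated[1], status = "FP",
        matched_prediction = paste(unrelated, collapse = "; "))
    }
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else {
    tibble::tibble(pmid = character(0), design = character(0),
                   status = character(0), matched_prediction = character(0))
  }
  list(counts = list(tp = tp, fp = fp, fn = fn),
       metrics = compute_metrics(tp, fp, fn),
       report = report)
}
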