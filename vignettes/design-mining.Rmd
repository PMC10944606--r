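---
title: "Mining reported study designs from biomedical abstracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining reported study designs from biomedical abstracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(designminer)
```

## The problem

Epidemiological abstracts state their study design -- when they state it at
all -- in a small set of semi-frozen phrasings: "we conducted a
cross-sectional study", "this was a randomised controlled trial", "a
prospective cohort study was performed". designminer exploits that regularity
with a deliberately simple, fully inspectable pipeline:

1. **Ingest** PubMed XML or MEDLINE flat text into a validated corpus of
   abstracts (`read_pubmed_xml()`, `read_medline()`).
2. **Extract** design mentions with a dictionary of design terms embedded in
   anchor-pattern rules (`extract_mentions()`).
3. **Standardize** each abstract to one canonical design, factored into a
   lower-level design plus descriptive attributes and classified into five
   high-level nodes (`standardize_designs()`).
4. **Align** the result with the hierarchy of scientific evidence
   (`assign_hierarchy()`).
5. **Evaluate** extraction at the abstract level with precision, recall and
   F1 (`evaluate_corpus()`), and **aggregate** into frequency and trend
   tables (`tabulate_designs()`, `trend_by_year()`).

A synthetic abstract generator (`generate_corpus()`) makes every stage
testable end to end without network access.

## The dictionary and classification schema

The shipped lexicon (`inst/extdata/design_lexicon.yaml`) holds exactly 134
design terms spanning experimental (trials), observational and secondary
(reviews, meta-analyses) designs. The reference dictionary this reconstructs
is not public in full, so the shipped set was assembled from the
classification schema's lower-level designs, the designs and attributes
observed in the reference frequency tables, and standard epidemiology
vocabulary, padded to the documented size of 134; the config file is
user-replaceable and `load_lexicon()` validates any file with the same
layout.

Matching is case-insensitive. Each term is expanded to a closure of surface
variants under three alternations (`expand_variants()`): British/American
spelling (randomised/randomized), hyphen/space between tokens (closed forms
like "crosssectional" are deliberately excluded; genuinely attested closed
compounds such as "nonrandomised" are listed per entry), and singular/plural
of the head noun. Matching is leftmost-longest: at any position the longest
dictionary term wins, so "This prospective cohort study" yields "prospective
cohort", not "cohort".

The schema maps each lower-level design to one of four substantive nodes --
observational, trial, review, meta-analysis -- with a fifth, miscellaneous,
for phrases too ambiguous to classify ("analytical study", "systematic
approach", "clinical"). Three deliberate irregularities are flagged in the
config rather than hidden:

* **Dual-role labels.** "case series", "natural experiment", "interrupted
  time series" and "comparison" act both as designs and as attributes. A
  standalone mention standardizes to the design; as a leftover token next to
  another design it becomes that design's attribute.
* **Qualifier-only sub-types.** "quantitative", "qualitative" and
  "comparison" are listed as meta-analysis sub-types but are never matched as
  bare phrases: a "qualitative study" is not a meta-analysis. They classify
  only in compound form ("qualitative meta-analysis").
* The attribute vocabulary extends the documented minimum with attributes the
  reference results tables themselves use ("clinical", "multicentre",
  "placebo controlled", ...), because design/attribute factoring fails
  otherwise on common compounds such as "randomised clinical trial".

## The rule set

Twenty positive rules and three negative rules live in
`inst/extdata/design_rules.yaml`; rules are data, so the set can be edited
and re-validated (`validate_rules()`) without touching code. Each rule is an
anchor regex of semi-frozen lexical expressions plus one design slot filled
by the dictionary. Only examples of the original rule set are public, so the
shipped twenty were reconstructed from the described anchor style
(verb/noun-phrase/preposition frames such as "we conducted a", "this was a",
"<design> study was performed", structured-abstract "DESIGN:" labels).

Numerical and procedural choices, all of which were genuinely open:

* **Window.** An anchor and its slot may be at most 6 tokens apart (so "we
  conducted a six year follow up of a <design>" is still seen -- and then
  vetoed, see below). Most rules use tighter windows (0-3).
* **Sentence-bounded.** Matching runs sentence by sentence
  (`segment_sentences()`, with abbreviation guards for "e.g.", "i.e.",
  "vs.", initials); mentions never cross sentence boundaries.
* **Priority.** When several rules fire on the same span the lowest rule id
  wins; duplicate (surface, span) pairs collapse; the same design at
  different spans is kept.
* **Negative contexts.** References to previously implemented studies are the
  dominant false-positive source for this kind of extractor. Three negative
  rules veto any slot in their window: "follow up of a <design>",
  "following a <design> ..." and "protocol for a <design>". A negative rule
  can only ever remove mentions (tested as a monotonicity property).
* **Spans** are 0-based, half-open character offsets on the abstract text.
  Structured-abstract section labels are kept in the text as "LABEL: "
  prefixes -- anchors legitimately match inside METHODS sections, and the
  "DESIGN:" label is itself an anchor. Titles are not scanned by default
  (`scan_titles = FALSE` in `extract_mentions()`).

## Standardization and unification

`canonicalize()` lowercases, opens closed compounds, unifies hyphens/solidi
to spaces (re-hyphenating only the meta- family: meta-analysis,
meta-analytic), and maps American -iz- spellings to British -is-. It is
idempotent.

When an abstract has several distinct mentions, the **lengthiest** canonical
phrase is kept as the representative, on the assumption that the longest
phrase is the most informative ("randomised double blinded controlled trial"
over "randomised controlled trial"). Length is measured after dropping the
generic tokens "study", "design", "of", "a" -- so "prospective cohort" beats
"cohort study" -- and ties break to the earliest text position, which makes
the choice deterministic and order-invariant (property-tested over random
permutations). All mentions are retained in an `all_mentions` audit column so
unification loses nothing mechanically checkable.

`split_design_attributes()` factors the canonical phrase greedily: strip
trailing generic head nouns, find the longest schema design whose tokens
appear in order in the phrase such that every leftover token is consumed by
the node's attribute vocabulary, and route to miscellaneous when no factoring
consumes everything. Greedy longest-match keeps compound designs like "cross
sectional descriptive" intact instead of over-factoring them.

## Hierarchy alignment

Tiers, top to bottom: meta-analysis; systematic review; randomised controlled
trial (including cluster and individually randomised); non-randomised and
controlled trials plus quasi-experimental designs; cohort; case-control;
cross-sectional, survey, ecological and descriptive; case report and case
series. Miscellaneous designs, and designs no tier admits, are labelled
**unmappable**. Bare "randomised" is deliberately unmappable (a "randomised
design" alone does not establish an RCT), while "cluster randomised" and
"individually randomised" sit in the RCT tier. Tier membership is config,
not code, because reasonable analysts bin the middle of the pyramid
differently.

## Evaluation conventions

Scoring is at the abstract level. A gold design counts as detected (TP) if
*any* related mention was extracted, where related means canonical equality
or token-wise containment either way ("cohort study" detects "prospective
cohort"); a gold design all of whose mentions were missed is an FN; each
group of mutually related predictions unrelated to every gold design is one
FP.

All percentages in the package -- metrics and tables alike -- are **truncated
(floored) to one decimal, and F1 is the harmonic mean of the truncated
precision and recall, itself truncated**. This is the unique convention under
which the reference evaluation table recomputes exactly from its integer
counts (e.g. 62/68 = 91.17... reported as 91.1). One consequence is worth
stating plainly: the reference corpus proportions mix conventions -- the same
denominator yields 2,319/13,671 = 16.9 only by truncation but
190/13,671 = 1.4 only by rounding -- so no single convention reproduces every
reported cell; this package truncates consistently and reports 1.3 for the
latter. Undefined metrics (zero denominators) are reported as `NA`, never
as 0. Every table states its denominator explicitly.

## The synthetic generator

`generate_corpus()` emulates the study conditions the pipeline is meant for:

* 40% of abstracts state a design (`p_no_design = 0.6`), matching the
  observed share of abstracts with an extractable design;
* design frequencies follow the observed head-heavy lower-level distribution
  (systematic reviews and randomised controlled trials dominate), attribute
  frequencies the observed attribute counts, and about 47.5% of designs carry
  an attribute-laden surface form (`p_attribute`), matching the observed
  share of attribute-bearing designs;
* a stated design is repeated as a partial mention ("prospective cohort" ...
  "cohort") with probability 0.25, and an adversarial prior-study phrase
  ("follow up of a <design>" with a design unrelated to the abstract's own)
  is inserted with probability 0.15;
* publication years span 1963-2023; one seeded RNG stream drives everything,
  so corpora are byte-identical across runs with the same seed.

Abstracts are template-filled English around exactly the anchor phrasings the
shipped rule set declares. That is the point -- the closed loop
(generate, extract, standardize, evaluate = 100/100/100) verifies the
machinery, not real-world accuracy. The generator does **not** emulate
free-form prose, unseen anchor phrasings, designs missing from the
dictionary, non-English text or OCR noise, so passing tests bound extractor
correctness on covered phenomena and say nothing about recall on novel
phrasing. `corrupt_predictions()` complements it by producing imperfect
predictions together with the exact TP/FP/FN counts its own coin flips imply,
which pins the scorer to an independent oracle.

Test and acceptance runs use corpora of 25-500 abstracts; 500 exercises every
injected phenomenon many times over while keeping a full pipeline run around
half a minute.

## Known limitations

* The shipped dictionary and rule set are reconstructions at the documented
  sizes (134 terms, 20 positive rules), not the original artefacts; both are
  config files meant to be replaced or extended.
* Containment-based relatedness treats "non randomised trial" as related to
  "randomised trial"; with negation-aware gold annotations you may want a
  stricter predicate.
* The extractor identifies the *stated* design only; it does not infer
  designs from indirect cues (control groups, sampling language), extract
  participant counts, interventions or outcomes, and it processes English
  text only.
* Evidence-hierarchy binning of mid-pyramid designs is conventional; edit the
  hierarchy block of the lexicon config to match your preferred pyramid.
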