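# Syntactic pattern rules: semi-frozen lexical anchors around a dictionary
# design slot. 20 positive (extracting) rules, 3 negative (suppressing) rules
# for prior-study and post-hoc-analysis contexts. Anchors are case-insensitive
# regexes; `position` says whether the anchor precedes or follows the slot;
# `window` is the maximum number of tokens between anchor and slot;
# `after_req` must match immediately after the slot. Rules are data: edit and
# revalidate with validate_rules().
rules:
  - id: r01
    polarity: positive
    position: before
    window: 6
    anchor: "we (conducted|performed|undertook|carried out) (a|an)\\b"
  - id: r02
    polarity: positive
    position: before
    window: 2
    anchor: "we (conducted|performed|undertook|carried out) (this|the present)\\b"
  - id: r03
    polarity: positive
    position: before
    window: 3
    anchor: "this (was|is) (a|an)\\b"
  - id: r04
    polarity: positive
    position: before
    window: 0
    anchor: "\\b(this|the present|the current)\\b"
    after_req: "study|studies|trial|trials|survey|review|analysis|design"
  - id: r05
    polarity: positive
    position: before
    window: 3
    anchor: "we (report|describe|present) (a|an)\\b"
  - id: r06
    polarity: positive
    position: before
    window: 3
    anchor: "we (report|describe|present) the (results|findings|outcomes) (of|from) (a|an)\\b"
  - id: r07
    polarity: positive
    position: before
    window: 3
    anchor: "we (used|employed|applied|adopted) (a|an)\\b"
  - id: r08
    polarity: positive
    position: before
    window: 3
    anchor: "data (were|are) (drawn|obtained|derived) from (a|an)\\b"
  - id: r09
    polarity: positive
    position: before
    window: 3
    anchor: "(as part of|in the context of) (a|an)\\b"
  - id: r10
    polarity: positive
    position: before
    window: 2
    anchor: "(study )?design\\s*:\\s*"
  - id: r11
    polarity: positive
    position: before
    window: 3
    anchor: "(secondary|pooled) analysis of (data from )?(a|an)\\b"
  - id: r12
    polarity: positive
    position: before
    window: 3
    anchor: "participants were (recruited|enrolled) (in|into|for) (a|an)\\b"
  - id: r13
    polarity: positive
    position: before
    window: 3
    anchor: "patients were (recruited|enrolled|randomised|randomized) (in|into|to) (a|an)\\b"
  - id: r14
    polarity: positive
    position: before
    window: 2
    anchor: "using (a|an)\\b"
    after_req: "design|approach|method|methods|methodology"
  - id: r15
    polarity: positive
    position: after
    window: 3
    anchor: "(was|were) (conducted|performed|undertaken|carried out)\\b"
  - id: r16
    polarity: positive
    position: after
    window: 2
    anchor: "design was (used|chosen|adopted|employed)\\b"
  - id: r17
    polarity: positive
    position: before
    window: 0
    anchor: "(the )?(aim|objective|purpose) of this\\b"
    after_req: "study|trial|survey|review"
  - id: r18
    polarity: positive
    position: before
    window: 3
    anchor: "(was|were) (evaluated|assessed|examined|tested) in (a|an)\\b"
  - id: r19
    polarity: positive
    position: before
    window: 3
    anchor: "we (initiated|launched|began|set up) (a|an)\\b"
  - id: r20
    polarity: positive
    position: before
    window: 0
    anchor: "\\bour\\b"
    after_req: "study|design|trial|survey"
  # negative context: references to previously implemented studies or to
  # analyses performed after them must not yield a design for this abstract
  - id: n01
    polarity: negative
    position: before
    window: 6
    anchor: "follow(ed|ing)?[\\s-]*up (study )?of (a|an|the)\\b"
  - id: n02
    polarity: negative
    position: before
    window: 3
    anchor: "following (a|an)\\b"
  - id: n03
    polarity: negative
    position: before
    window: 6
    anchor: "protocol for (a|an)( future| planned)?\\b"
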