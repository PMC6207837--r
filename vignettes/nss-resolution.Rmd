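---
title: "Resolving non-specific structures: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving non-specific structures: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nssanchor)
```

## The task

Taxonomic morphological descriptions are written in a telegraphic
sub-language, largely without verbs, and make heavy use of part terms that do
not name an identifiable organ by themselves: *apex*, *base*, *margin*,
*surface*, *side*, and so on. We call these non-specific structure (NSS)
terms. Each NSS mention must be *anchored* to the organ it belongs to before
any character attached to it ("margin serrate") becomes a usable phenotype
statement. The anchor may precede or follow the mention, so the task
generalizes antecedent search: it is an associative (mereological) bridging
reference problem, not coreference.

`nssanchor` consumes *statements*: tokenized spans in which entity mentions,
of-phrase and possession relations have already been annotated by an upstream
fine-grained annotation tool. The package deliberately does no parsing or
entity recognition of its own; its input schema (JSON, with a minimal XML
dialect) records tokens with sentence indices, entity spans with a head
token, relations, and an optional gold map for evaluation.

## The soft part-of ontology

Formal anatomy ontologies exclude most NSS terms because part-of in the
'all-some' reading fails for them (not every apex is part of a leaf). The
ontologies used here are deliberately *soft*: an edge `apex part_of leaf`
asserts only that an apex could belong to a leaf, and the resolvers treat the
ontology as a licence filter over candidates, not as a reasoner.
`may_be_part_of(o, p, w)` is true when some term that is `p` or a transitive
subclass of `p` has a part-of edge to some term that is `w` or a transitive
subclass of `w`. Subclass expansion on the whole side is required so that a
compound entry like *elytron side* (subclass of *side*, part of *elytron*)
licenses the bare query (*side*, *elytron*).

Three deliberate choices:

* **part_of is single-hop.** `apex part_of leaf` and `leaf part_of shoot` do
  not license (*apex*, *shoot*) by default; chaining is available behind
  `transitive = TRUE` but never used by the resolvers. Soft constraints are
  curated per query, and chaining them multiplies false licences.
* **Name fallback.** Resolution creates compound names ("abdomen upper
  margin") and surface forms are often plural ("edges", "leaves"), so a query
  name absent from the ontology falls back to its head (last) word and then
  to a singularized head (with a small irregular table: *axes* to *axis*,
  *leaves* to *leaf*, ...). The same matching rule defines membership in the
  NSS lexicon, which is why "adaxial side" and "epidermal cells" count as NSS
  against the bare lexicon entries *side* and *cell*.
* **Self-parthood is never licensed**, even when a subclass of a term is a
  part of the term itself; a mention must not anchor to itself and letting
  (*x*, *x*) through would only ever license such degenerate candidates.

## The rule engine

Rules are tried in decreasing order of confidence — of-phrase, possession
words, window — and every candidate must additionally pass the ontology
filter. The first candidate surviving both tests wins; if none does, the
mention is left unresolved (`NA` anchor), which under evaluation costs recall
but not precision.

* **of_phrase**: governors of annotated of-phrase relations whose dependent
  is the mention ("base *of the leaves*").
* **possession**: governors of possession relations whose trigger is in the
  possession lexicon (default *with, contain, contains, containing, have,
  has, having*).
* **window**: every other entity within `window_size` sentence boundaries
  (default 3), closest first by head-token distance, preceding preferred on
  ties.

Two readings were genuinely open and are fixed as follows. "Within three
sentence boundaries" is read symmetrically — at most three boundaries between
candidate and mention in either direction — because anchors are explicitly
allowed to follow their mention; the unit (sentence index difference) and the
size are both exposed in `rule_config()`. Candidate order within a rule is
proximity-based with a preceding-entity tie-break rather than raw document
order; document order would make the window rule systematically prefer the
statement subject, which duplicates the subject baseline rather than the
locality evidence the window rule is meant to capture. The choice is
config-exposed (`candidate_order`).

When the winning candidate is itself an unresolved NSS it is pushed onto a
to-be-resolved stack and the cascade re-runs for it. On finding a non-NSS
anchor the stack unwinds, each popped mention receiving the accumulated
compound name, outermost organ first: in "abdomen has a thin edge at its
upper margin" the possession candidate *abdomen* fails the ontology test for
*edge*, the window rule proposes *upper margin* (licensed via its head word
*margin*), and the recursion yields *upper margin* → "abdomen" and *edge* →
"abdomen upper margin". A mention resolved as part of a chain is removed from
the work list and not revisited; a cyclic chain (a → b → a) leaves every
member unresolved with a warning. An NSS that failed to resolve can still
serve as a later mention's terminal anchor under its surface name — at that
point it is no longer on the work list, which mirrors the work-list semantics
of the cascade. The `ontology_only` variant forces `rule_order = "window"`.

## The pairwise SVM

Resolution is framed as pairwise classification: every (candidate, NSS) pair
in a statement is a training instance, positive exactly when the candidate's
name matches the gold anchor. Features come in three groups:

1. distance/position: candidate-is-subject, candidate-is-closest, absolute
   and relative token distance, absolute and relative entity count between
   the pair;
2. lexical: one indicator per connector (*in, on, at, of, has, have, with,
   contains, without*) occurring between the mentions, plus bag-of-words
   counts of tokens within `context_window` positions around each mention
   (connectors excluded, vocabulary frozen at training time to tokens with
   frequency at least `word_freq_threshold`);
3. semantic: ontology licence for the pair, candidate-is-NSS.

Defaults (`svm_config()`): polynomial kernel of degree 3, positive class
weight 7, frequency threshold 9, context window 4, five CV folds for
`tune_svm()`. The backend is the LIBSVM binding in `e1071` with Platt-style
probability estimates; all other solver parameters stay at their defaults,
and the solver seed is fixed from `random_seed` so training is reproducible.
Where the defaults leave room, the package reads them as follows: the class
weight applies to the positive class (positives are the minority of the
pairwise expansion, roughly one per candidate set); the context window is
symmetric, four tokens on each side of each mention; bag-of-words features
are counts, with a `bow_counts = FALSE` switch for binary indicators; tokens
unseen at training time are dropped. Excluded feature groups are absent from
the vector, not zeroed, so a groups-1-2 model is genuinely blind to the
ontology.

At prediction time the anchor of an NSS is the candidate with maximal
estimated probability over all other entity mentions of the statement. The
SVM always answers when a candidate exists, so its precision and recall
coincide. Probability ties — which do occur, because LIBSVM floors estimates
near 0 and 1 — are broken by smaller token distance, then earlier document
position. There is no SVM-side recursion; if the predicted anchor is itself
an NSS whose anchor was predicted in the same statement, the reported name is
expanded to the compound chain name (cycle-safe), mirroring the rule engine's
naming so the two methods are comparable under string-match evaluation.

A practical numerical note: Platt calibration needs a handful of points per
class. On a single statement (one positive, one negative pair) the
probability ordering can invert even though the decision function separates
the data; the test suite therefore exercises trivial separability with two
statements, the smallest configuration where calibration is stable.

## Evaluation

Scoring is micro-averaged over pooled NSS occurrences: `S` the non-null
system resolutions, `H` the gold occurrences, `P = |S∩H|/|S|`,
`R = |S∩H|/|H|`, F1 their harmonic mean (0 when both are 0). Correctness is
canonicalized string equality of the final anchor name — compound names must
match exactly — because gold annotates anchor *names*, and mention-identity
matching would mark a correct name on the wrong mention occurrence as an
error. Unresolved mentions leave `S` and therefore hit recall only; methods
that always answer necessarily have P = R = F1. `error_overlap()` partitions
the mistakes of two methods into A-only / B-only / both, and reconciles with
each method's own mistake total by construction.

## The synthetic generator

No annotated corpus for this task is distributable, so the package generates
one. `generate_corpus()` first fixes, per NSS term, the set of organs it may
belong to (three by default); the emitted ontology is exactly that
assignment, with about a quarter of the pairs encoded through a compound
subclass term (`"leaf margin" ⊑ margin, part_of leaf`) so the subclass
closure is exercised, plus a handful of NSS-to-NSS edges for chains.
Statements are then drawn from five telegraphic templates, each planting one
decisive signal: an of-phrase, a possession phrase, a window/proximity
configuration in which exactly one in-range candidate is licensed, a
two-NSS chain replicating the recursion example, and a "distractor" category
whose gold organ is neither mentioned nor licensed (unrecoverable by
construction; the rule engine abstains on it). The default mix is 35%
of-phrase, 25% possession, 25% window, 15% chain and no distractors, noise 0
— under these defaults every gold anchor is recoverable and the templates
make each planted rule decisive, which is what makes the per-rule unit tests
sharp. `noise` replaces a statement's gold organ with an unlicensed one, so
the ontology-constrained rule engine loses recall (not precision)
monotonically in expectation as noise grows. All randomness flows from a
single seed; identical configurations are byte-identical on disk.

What the generator does *not* emulate: free word order, real lexical
ambiguity, annotation errors in the upstream tool, NSS terms whose status
varies by taxon (e.g. *body*), and statements where several licensed
candidates compete inside the window. Perfect scores on noise-free synthetic
corpora therefore demonstrate correctness of the mechanisms — rule priority,
ontology filtering, recursion, argmax selection — not expected performance
on real descriptions, where candidate competition and ontology gaps dominate
the error budget.

One test-design note: a corpus whose gold anchor is *always* the subject
makes the subject baseline perfect and unbeatable, so the planted
subject-signal check trains the SVM on a possession+window mixture in which
the subject feature is informative but neither baseline is sufficient, and
requires the SVM to beat both baselines held-out.

## Problem sizes and determinism

The shipped tests and the acceptance script use corpora of 10–500 statements
(ontologies of up to ~60 terms; random ontologies of up to 30 terms for the
closure oracle), sizes at which every brute-force oracle — exhaustive
subclass-closure scans, full (rule, candidate) enumeration, per-pair
probability scans — runs comfortably while still covering every code path,
including multi-NSS chains and abstention. Every stochastic component
(generator, fold assignment, solver internals) is seeded explicitly, so all
reported numbers are exactly reproducible.

## Known limitations

* Relations arrive pre-annotated; a missing of-phrase annotation silently
  demotes a mention to the window rule.
* The possession rule trusts the annotated relation plus a trigger lexicon;
  it does not check clause structure.
* Compound anchors are space-joined names; no attempt is made to normalize
  them against the ontology's own compound terms beyond head-word fallback.
* The XML reader targets a minimal dialect, not any specific annotation
  tool's full export format.
* Lexicon membership via head-word singularization uses a small irregular
  table; unusual Latin plurals outside it will be missed.
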