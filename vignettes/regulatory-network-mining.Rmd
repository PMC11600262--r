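---
title: "Mining molecular regulatory networks from abstracts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining molecular regulatory networks from abstracts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litnet)
```

`litnet` extracts directed molecular relations — promotes, inhibits,
upstream, abbreviation, function — from biomedical abstracts and aggregates
them into a provenance-weighted regulatory knowledge graph. This vignette
is the package's own account of the models it implements, the parameters
that matter, the design choices made where the design was genuinely open,
and what the shipped tests do and do not establish.

## The document model

Text is segmented by deterministic rules: sentences end at `.`, `!` or `?`
followed by whitespace and an uppercase letter, digit or opening bracket,
unless the preceding word is on a short abbreviation stoplist ("e.g.",
"et al.", "Fig." and the like); tokens are whitespace chunks with leading
and trailing punctuation split off, keeping internal hyphens so `WNT-4`
remains one token. A rule-based tokenizer was chosen over a statistical one
because every downstream artifact (gold spans, interaction maps, graph
provenance) is keyed by token indices, and reproducibility of offsets
matters more here than segmentation finesse. Conventions: character
offsets are 0-based half-open; entity spans are token-index spans within
one sentence; entities never cross sentence boundaries (relations in this
domain are overwhelmingly intra-sentential, and the relation stage is
per-sentence anyway).

Annotated corpora travel as JSONL, one document per line, with entities as
`(sentence, start, end, label)` token spans and relations referencing
entity indices. The reader validates strictly and reports the offending
line number.

## The entity tagger

The tagger is a classical neural sequence labeller over the nine-tag BIO
alphabet (`O` plus B/I for each of Gene, SignalPathway, Cancer,
BiologicalFunction):

* **Embedding providers.** Token representations come from pluggable
  providers: a trainable lookup table (default 24 dimensions) and a
  deterministic character-window provider (16 dimensions: four word-shape
  flags plus L2-normalized hashed character trigrams). The provider
  contract — tokens in, one fixed-dimension vector per token — lets users
  substitute pretrained contextual embeddings; the shipped providers are
  deliberately small and self-contained so the package has no model-weight
  dependencies.
* **Merge and encoder.** Provider outputs are concatenated and passed
  through a linear merge layer (default 24 units), then a single-layer
  bidirectional recurrent encoder (default 16 hidden units per direction).
  The default cell is a plain tanh recurrence; a GRU is available as
  `recurrence = "gru"`. At these corpus scales the gated variant buys
  nothing measurable, but the switch exists because long-range
  dependencies in real abstracts may warrant it.
* **CRF output layer.** Emission scores feed a linear-chain CRF. Training
  minimizes the negative conditional log-likelihood, `log Z(x) -
  score(x, y_gold)`, with the log-partition computed by the forward
  algorithm and its gradient by forward–backward expected counts; all
  gradients in the package are hand-derived and verified against numerical
  differentiation in the test suite. Decoding is Viterbi with a hard BIO
  mask (transitions into `I-X` are only possible from `B-X`/`I-X`, and no
  sequence may start with `I-X`), so decoded output is well-formed
  regardless of training quality. The mask is applied at decode time only;
  the partition function deliberately sums over all sequences, keeping the
  training objective the standard conditional likelihood.
* **Optimization.** Per-sentence Adam updates (default learning rate 0.02,
  20 epochs). One integer seed drives initialization and epoch shuffling;
  two runs with the same seed are bit-identical.

Ill-formed predicted BIO (an `I-X` with no preceding `B-X`) is repaired by
promoting the offending tag to `B-X` — a lossless repair that keeps
evaluation well-defined; with masked decoding it can only be triggered by
externally supplied tag sequences.

## The relation extractor

Relations are extracted jointly over a *unified interaction map*: a square
matrix over the sentence's `L` tokens plus `K = 5` relation slots in the
fixed order Promotes, Inhibits, Upstream, Abbreviation, Function. A gold
triple `(s, r, o)` sets exactly three cells — `(head(s), head(o))`,
`(head(s), slot(r))` and `(slot(r), o)` — with row = relation slot and
column = object for the relation–object cell (the row/column convention is
fixed here and serialized with the model; nothing downstream depends on
the opposite choice). A span is anchored by its **first token**; full
spans are restored later by the integrator, which is why the extractor can
work at head granularity without losing boundary information.

The scorer projects unit representations (contextualized tokens and
learned slot embeddings) into a query and a key space (default 24
dimensions each) and applies a sigmoid to their scaled dot products. The
token encoder reuses the tagger's provider + bidirectional recurrence
stack: with purely lexical (non-contextual) lookup embeddings the
subject/object role of a gene mention would be undecidable — the same
symbol appears in both roles across a corpus — so role information must
come from context, exactly what the recurrent pass supplies. Training
minimizes mean elementwise binary cross-entropy against the gold map,
again with per-sentence Adam (default learning rate 0.005, 40 epochs; the
lower rate keeps the heavily class-imbalanced BCE objective from
collapsing into the all-zeros map early in training). Decoding emits
`(s, r, o)` iff all three cells reach the threshold `tau` (default 0.5,
configurable); raising `tau` provably never enlarges the decoded set.
Sentences longer than `max_tokens` (default 120) are skipped with a
warning — inputs are pre-split per sentence, so this is a guard rail, not
a working regime.

Decoding the *union* of cell sets is lossy in one direction only: when
several gold triples share heads, spurious combinations can satisfy the
three-cell rule. The tests therefore assert containment (every planted
triple is recovered) plus exactness for non-interacting triples, and the
brute-force `(s, r, o)` enumeration oracle confirms the decoder on random
maps.

## Integration

The integrator fuses NER spans with RE head-triples: a candidate survives
iff both heads fall inside recognized entity spans of the same sentence
and the `(subject label, predicate, object label)` combination is allowed.
Integration is a pure filter — output is always a subset of the anchored
candidates — which is the mechanism behind precision improving when the
two stages are combined. The default compatibility table encodes
conservative biology: regulatory predicates require a Gene or
SignalPathway subject; Function links only Gene/SignalPathway to
BiologicalFunction; Abbreviation is allowed only between mentions of the
same entity type. One combination is hard-forbidden even in user-supplied
tables: a Gene/BiologicalFunction abbreviation in either direction, which
is semantically impossible. Everything else is overridable via a TSV.

## The knowledge graph

Aggregation normalizes every mention (gene aliases resolve
case-insensitively through a gene_info-style synonym table; unknown genes
and non-gene entities become their case-folded, whitespace-collapsed
surface), drops self-loops created by normalization (with a warning — a
"WNT4 promotes Wnt-4" triple is an extraction artifact, not biology), and
merges identical normalized triples into one weighted edge.

Open choices resolved here:

* **Mention-level frequency.** Edge weight counts distinct
  (document, sentence) supports, not distinct publications: the same fact
  stated twice in one sentence counts once, but two sentences in one paper
  count twice. Publication-level counts are recoverable from the
  provenance list.
* **Abbreviation triples are not edges.** They extend the synonym lookup
  within the aggregation's scope (the object surface becomes an alias of
  the normalized subject), which is what keeps node identifiers unique;
  Function triples, by contrast, stay as Gene → BiologicalFunction edges.
* **Ambiguous aliases** (one alias claimed by several symbols) are left
  unresolved — the surface form stays its own node — rather than guessing
  an identity; a warning lists them. Standard symbols always resolve to
  themselves.
* **Missing years** pass year filters (inclusive-by-default) since absence
  of metadata is not evidence of being out of range.

Filters (predicate set, minimum weight, year range) compose commutatively
and prune orphaned nodes. Intermediary queries enumerate directed simple
paths up to `max_len` edges using only regulatory predicates, ranked by
path length then minimum edge weight (the weakest link bounds a path's
support); the enumeration is checked against igraph's all-simple-paths as
an independent oracle.

## Statistics

* **Pearson edge confidence** uses `stats::cor` on the endpoint expression
  profiles; bands on `|r|` default to weak < 0.3 ≤ moderate < 0.6 ≤ strong
  (configurable — the cut points are conventional, not fitted).
* **Median-split rank-sum:** samples split at a gene's median (ties to the
  low group, which keeps even-n splits deterministic), Mann–Whitney U on a
  second gene. The p-value is exact by enumeration of all
  `choose(n, n_high)` assignments when combined n ≤ 20 — this handles ties
  correctly, which the classical exact distribution does not — and the
  tie-corrected normal approximation otherwise. The two-sided exact p is
  the permutation probability of a U at least as far from `n1·n2/2` as
  observed; the permutation distribution of U is symmetric, so this equals
  the doubled smaller tail.
* **Wilson score intervals** for precision/recall: the closed form with
  `z = 1.959964` at 95%. The interval never leaves `[0, 1]` and always
  contains `k/n`; the test suite cross-checks it against
  `prop.test(correct = FALSE)`.
* **McNemar:** exact doubled binomial tail (capped at 1) below 25
  discordant pairs, continuity-corrected chi-square above. Zero discordant
  pairs returns p = 1 with a warning rather than an error, since paired
  designs with perfect agreement are a legitimate, if uninformative,
  outcome.
* **Matching** is exact-boundary, exact-label (exact subject span,
  predicate and object span for triples), one-to-one, micro-averaged by
  pooling counts across classes. Zero denominators define the metric as 0
  with a warning.

## The synthetic corpus

The generator emits documents of 2–5 templated sentences. Each relation
predicate has one template emitting exactly one gold triple (so the
relation mix maps one-to-one onto emitted predicate frequencies), plus a
distractor template with entities but no relation, giving the BCE
objective true negatives. Default study conditions, chosen once: uniform
relation mix, alias probability 0.3, distractor probability 0.25,
publication years 2010–2024, document split 70/15/15 by document. The gene
vocabulary is synthetic (`GENA1`, …) plus WNT4, STAT3 and IGF2 with
realistic aliases, so the intermediary-query demonstration runs out of the
box. Expression matrices are multivariate-normal draws with a planted
correlation structure; the default plants 0.9 on WNT4–STAT3 and
STAT3–IGF2 (and the implied 0.81 on WNT4–IGF2) over 14 samples, the scale
of a small patient cohort.

What passing tests on this corpus establishes — and what they do not: the
templated language is fully separable, so held-out F1 near 1.0 shows the
architecture, training loop, decoding and integration are implemented
correctly end-to-end. It says nothing about performance on real abstracts,
whose lexical variety, nested entities, coordination and hedging are
exactly what the templates omit. The thresholds used in the end-to-end
check (entity micro-F1 ≥ 0.90, integrated triple F1 ≥ 0.85 at 300 training
/ 100 test documents) are deliberately below the typical observed values
so that the check fails only on genuine regressions, not on seed jitter.

## Numerical and scale choices

Problem sizes in the shipped tests and the acceptance script were chosen
to exercise every code path at desk scale: CRF oracle checks enumerate all
`T^L` paths at `L ≤ 5, T ≤ 9`; interaction-map oracle checks run brute
force over maps up to side 16; the end-to-end run trains on 300 documents
(≈ 1000 sentences) for 12 (NER) and 30 (RE) epochs. BCE probabilities are
clamped at `1e-12` before logs; the log-partition uses the standard
max-shift logsumexp; Viterbi breaks score ties by lowest tag index, fixed
and documented so decoding is deterministic. Model checkpoints are single
RDS files carrying weights, vocabularies and configuration.

## Known limitations

* No coreference, negation or hedge handling: "WNT4 does not activate
  IGF2" yields a Promotes-shaped candidate that only downstream curation
  can remove.
* The RE stage anchors spans at head tokens; two distinct same-sentence
  mentions sharing a head token (rare under this tokenizer) cannot be
  distinguished.
* Alias resolution is string-based; species disambiguation and identifier
  mapping beyond the synonym table are out of scope.
* The shipped embedding providers are intentionally small; matching
  published extraction quality on real text requires plugging in
  pretrained contextual embeddings through the provider interface.
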