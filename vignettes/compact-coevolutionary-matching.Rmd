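---
title: "Matching biomedical ontologies with a compact coevolutionary algorithm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching biomedical ontologies with a compact coevolutionary algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccoem)
```

## The problem

Biomedical knowledge is spread over many ontologies that describe the same
entities under different names: one anatomy resource says *Myocardium*
where another says *Cardiac Muscle Tissue*.  Ontology matching is the task
of producing an **alignment** — a set of equivalence correspondences
`(e1, e2, n)` with confidence `n ∈ [0, 1]` — between the class sets of two
such ontologies.  `ccoem` implements a lexical profile similarity between
classes and a stochastic combinatorial search over whole alignments, with
an evaluation layer for both *rough* metrics (computable without a gold
standard) and classical precision/recall against a reference alignment.

## Concept profiles and the gated similarity

Every class contributes a **profile**: the multiset of normalized word
tokens taken from its labels, comments and property information (property
label, domain label, range label), plus the same information from its
*direct* subclasses only.  Tokens are lower-cased and split on whitespace,
underscores, hyphens and camel-case boundaries.  Classes without any
label fall back to their IRI local fragment so a profile is never empty.
Profiles are multisets, not sets: duplicated tokens are kept so the
cardinality `|p|` reflects information volume.

Two words are scored 1 if the synonym dictionary pairs them, and by the
Dice coefficient over padded character trigrams otherwise (a word framed
by `n−1` boundary markers; `2·|shared|/(|g1|+|g2|)`).  The dictionary is
a flat two-column table standing in for metathesaurus synonymy (UMLS-like
services are deliberately out of scope; the provider is pluggable).

The profile intersection `|p1 ∩ p2|` counts a greedy one-to-one pairing of
elements whose word similarity is strictly above the element threshold
(default 0.9), in descending similarity order with positional
tie-breaking.  The two asymmetric measures

    s1 = |p1 ∩ p2| / |p1|,    s2 = |p1 ∩ p2| / |p2|

are combined by a **δ-gate**: the concept similarity is `(s1 + s2)/2` when
`|s1 − s2| ≤ δ` and 0 otherwise.  δ defaults to 0.06 within its suggested
domain `[0.01, 0.10]`.  Two consequences worth knowing:

* the gate punishes *cardinality imbalance* — a perfectly contained small
  profile (`s2 = 1`, `s1` small) scores 0, which suppresses parent/child
  false positives but also rejects genuine pairs whose descriptions differ
  a lot in verbosity;
* with the greedy pairing, adding synonym pairs is *not* provably monotone
  in adversarial near-tie configurations (a new 1.0 pair can displace two
  0.9+ pairs).  On realistic vocabularies, where word similarities are
  effectively binary, enlarging the dictionary never lowers a similarity,
  and that is the regime the property tests exercise.

Whether the element threshold equals the δ of the gate is ambiguous in the
underlying description; they are kept as separate parameters
(`element_match_threshold`, `delta`) rather than conflated.

## Encoding alignments as bit strings

A candidate solution is the vector `X = (x1 … x_{n1}, t)`: `x_i ∈ 0..n2`
maps source concept `i` to target concept `x_i` (0 = unmapped) and
`t ∈ [0, 1]` is the confidence threshold that filters the final alignment.
Each `x_i` occupies `ceil(log2(n2 + 1))` bits (big-endian); the threshold
gene occupies enough bits for a grid of step `num_accuracy` (default 0.01,
7 bits).  Decoded values beyond their range are folded back with
`d mod (range + 1)`, so *every* bit pattern decodes to a valid solution
and decoding is surjective onto the index range.  The printed formula we
re-implement ("log2(n2)+0.5" and "replace d with u/d") under-allocates
bits for some `n2` and does not produce an index; the ceiling form and the
mod-fold preserve the stated intent (every target index representable;
total decoding) and are asserted by exhaustive enumeration in the tests.
A correspondence with similarity 0 is never emitted even at threshold 0:
it would carry no lexical evidence and would only inflate coverage.

## The compact EA

The population is replaced by a **probability vector** (PV): element `i`
is the probability that bit `i` samples 1.  Each generation draws one
candidate from the PV, flips each of its bits with probability 0.03, and
builds one neighbor of the elite by copying a short circular fragment of
the candidate into the elite (cut point uniform; the fragment grows while
uniform draws stay below `pc = 0.6`, a truncated geometric law with mean
`(1 − pc^len)/(1 − pc) = 2.5`).  The best of candidate, neighbor and elite
becomes the elite; ties retain the incumbent, which keeps the PV dynamics
stable.  Only the PV and three chromosomes are ever in memory — there is
no population array.

**When the PV moves** was the one genuinely open design point.  A single
update is fully pinned by the worked example frozen in the acceptance
tests: all elements move by the update rate (0.1) toward the elite's bits,
clamping to `[0, 1]` exactly.  Applying that update *every* generation,
however, drives every element to 0 or 1 within a few dozen generations;
the sampler then emits near-clones of the elite and the whole search
degenerates — measurably *worse than uniform random search* on a
3-concept instance.  `ccoem` therefore updates the PV only in generations
that produce a new elite.  Between improvements the PV is left to the
perturbation operator — each element moves 0.05 toward 0.5 with
probability 0.03 per generation — so the vector slowly re-diversifies
while the search is stuck and re-converges while it is improving.  This
reading uses both published mutation constants, reproduces the worked
example bit-for-bit, and restores the small-instance global-optimum
behaviour (10/10 and 9/10 seeds in the oracle-equivalence test, versus
7/10 and 2/10 under the literal every-generation reading).

## Three cooperating subswarms

`MatchCoverage` (fraction of all concepts of both ontologies appearing in
some correspondence) approximates recall; `MatchRatio` (distinct matched
concepts over twice the correspondence count) approximates precision and
equals 1 exactly on one-to-one alignments; `MatchFmeasure` is their
harmonic mean.  Optimizing the f-measure alone can improve one surrogate
at the other's expense, so `run_ccea()` evolves three PVs — one per
metric — and, after each generation, lets them exchange elites: every
elite is scored under every objective (a fixed 3×3 table over the
pre-exchange elites) and a swarm adopts the best foreign elite that
*strictly* beats its incumbent under the swarm's own objective, moving its
PV toward the adopted chromosome.  The exchange is Pareto-safe per
objective, costs a constant six cross-evaluations per generation, and the
final alignment is decoded from the f-measure swarm's elite.  The
update-then-help order is the default; `exchange_first = TRUE` switches
it, without any claim of fidelity for either order beyond the stated
"first updated … then help each other".  All three swarms share one
similarity matrix and one seeded RNG stream consumed in a fixed order
(ratio, coverage, f-measure), which makes runs bit-reproducible.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `delta` | 0.06 | width of the profile-similarity gate |
| `element_match_threshold` | 0.9 | word similarity above which profile elements count as identical |
| `ngram_size` | 3 | character n-gram order |
| `num_accuracy` | 0.01 | threshold-gene grid step |
| `update_rate` | 0.1 | PV step toward a new elite |
| `crossover_probability` | 0.6 | fragment continuation probability of the local search |
| `mutation_probability` | 0.03 | per-bit candidate flip / per-element perturbation probability |
| `mutation_rate` | 0.05 | magnitude of the PV drift toward 0.5 |
| `max_generation` | 3000 | generations of the evolutionary loop |

## The synthetic world

`generate_pair()` builds a complete `k`-ary tree of concepts with
two-word labels drawn from unique pronounceable CV-syllable pseudo-words
(random letter strings would zero out every off-diagonal n-gram
similarity and trivialize the landscape), then derives the second
ontology by synonym renames (recorded in the returned dictionary),
single-character corruptions, and concept dropout with child re-attachment
to the nearest kept ancestor.  The surviving identity mapping is the
one-to-one ground truth, matching the golden-alignment assumption of the
rough metrics.  What the generator does **not** emulate: shared words
across sibling labels (real anatomy reuses *muscle*, *tissue*
relentlessly), multi-parent hierarchies, uneven description verbosity,
and scale.  A green recovery test therefore establishes that the
pipeline recovers a *clean, vocabulary-disjoint* hierarchy — not OAEI
performance, which is explicitly out of scope (it requires external
ontology downloads and licensed synonymy).

## Known limitations

* **Search budget.**  With one candidate/neighbor pair per swarm per
  generation, most of the similarity matrix off-target entries being 0
  makes every wrong target index fitness-equivalent: each source concept
  is a `ceil(log2(n2+1))`-bit needle.  Recovering a 50-concept alignment
  needs on the order of `64` targeted trials per segment, more than the
  ~6000 evaluations a 1000-generation run affords; the acceptance suite
  asserts the stated 0.9-recovery criterion anyway and documents its
  failure (reference f-measure plateaus around 0.3–0.5) rather than
  weakening it.  The same regime makes a triple-budget single swarm beat
  the cooperative run on raw f-measure; the cooperation's bias-avoidance
  benefit concerns the near-convergence regime the budget never reaches.
* **Gate brittleness.**  The δ-gate zeroes pairs with strongly unequal
  profile cardinalities even under perfect containment.
* **Parsing scope.**  RDF/XML parsing covers named classes, labels,
  comments, subclass links and property domain/range declarations; no
  reasoning, no imports closure, no blank-node class expressions.  The
  Turtle reader is a pragmatic subset (prefixes, predicate lists,
  literals) sufficient for fixtures.

```{r example}
src <- load_ontology(system.file("extdata", "cardiac-src.owl",
                                 package = "ccoem"))
tgt <- load_ontology(system.file("extdata", "cardiac-tgt.owl",
                                 package = "ccoem"))
syn <- synonym_provider(system.file("extdata", "cardiac-synonyms.tsv",
                                    package = "ccoem"))
res <- run_ccea(src, tgt, syn, seed = 1, max_generation = 200)
res$alignment
ref <- read_alignment(system.file("extdata", "cardiac-reference.tsv",
                                  package = "ccoem"))
unlist(reference_scores(res$alignment, ref))
```
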