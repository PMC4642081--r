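---
title: "Approximate subgraph matching for biomedical event extraction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Approximate subgraph matching for biomedical event extraction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmevents)
```

## The problem

A biomedical *event* is a typed interaction anchored to a trigger word, with
role-labeled arguments (Theme, Cause, ...) that are either annotated
entities (proteins, genes) or other events — nesting is the norm:
"ligation of CD3 leads to phosphorylation of IkBa" expresses a
Positive_regulation whose Theme and Cause are themselves events. `asmevents`
extracts such events from dependency-parsed text by instance-based
reasoning: dependency subgraphs connecting triggers to arguments are learned
from annotated training sentences and matched approximately against new
sentences.

## Pattern induction

For every annotated event we collect the shortest undirected dependency
paths from the trigger to each argument (all paths of minimal length, so a
sentence in which two one-edge paths connect "lead" and "ligation" yields
two alternatives). Each (argument, path) pair becomes an *individual*
pattern; multi-argument events additionally yield *union* patterns, one per
combination of per-argument path choices. Individual paths raise recall;
unions raise precision through joint inference. Entity mentions are
anonymized to a generic type string first, so patterns abstract away the
specific protein. Sub-event arguments are represented by their trigger
token; multi-token triggers contribute their pairwise connecting paths.

Two choices here were genuinely open:

* **Union enumeration.** When several equal-length paths exist per
  argument, we enumerate the full cross-product of per-argument choices
  (the bundled worked example accordingly yields two union patterns),
  capped at `max_unions = 8` per event to bound blow-up.
* **All-paths mode.** "All possible lengths" is unbounded in general
  graphs; `all_paths` mode caps path length at the shortest length plus
  `extra_len = 2` (configurable). The pattern set grows by roughly a factor
  of two on nested corpora, matching the reported behaviour qualitatively.

Duplicate patterns are removed by exact isomorphism: a bijection must
preserve matchable node content (lemma, relaxed POS, entity type), every
labeled directed edge, and every role binding.

## The subgraph distance

A pattern graph G_r matches a sentence graph G_s through an injective
mapping f of its nodes onto sentence tokens with

```
subgraphDist = w_s * structDist + w_l * labelDist + w_d * directionalityDist
             + w_n * nodeDist
```

where per pattern edge, against the shortest undirected sentence path
between the endpoint images: `structDist` accumulates the extra path length,
`labelDist` counts label mismatches, and `directionalityDist` orientation
mismatches; `nodeDist = |skipped| / |V_r|` penalizes non-essential pattern
nodes left unmapped. Essential nodes (trigger, sub-event trigger, argument
nodes) can never be skipped; with nothing skipped the extended distance
equals the original three-component form. A match is accepted when the total
is at most the threshold `t`; smaller `t` means stricter isomorphism.

Numerical and tie-breaking choices:

* The multi-hop alignment rule (not fixed by the ASM distance definition
  itself): among shortest paths we take the one minimizing
  `labelDist + dirDist`, further ties by lexicographic node order;
  for a one-edge path the label and orientation are compared directly, for
  a longer path `labelDist` flags the pattern label being absent from the
  path and `dirDist` the absence of a consistently oriented edge with that
  label. The rule is concentrated in one internal routine
  (`ctx_align_cost`) so an alternative (e.g. per-hop label counting) is a
  one-point change.
* Node matching uses the `P*+L` criterion by default: identical relaxed POS
  (all `NN*` collapse to `NN`, all `VB*` to `VB`) and identical lemma.
  Entity-bound nodes match only entity tokens of the same generic type.
* Weights default to 1 with the equal-weights constraint
  `w_s = w_l = w_d = w_n`, so integer thresholds count unit differences:
  `t = 1` tolerates one label or direction change. (Configurations scaled
  by a factor, e.g. all weights 10, only rescale thresholds.)
* The search enumerates candidate images depth-first with branch-and-bound
  on the running total — exact because every component contribution is
  non-negative — and returns, per distinct essential-node image, the single
  minimal match (ties: fewest skipped nodes, then lexicographic image).
  A brute-force enumerator (`brute_force_matches`) serves as the oracle in
  the tests.
* Floating-point threshold comparisons carry a 1e-9 tolerance.

## Bottom-up extraction and consolidation

Patterns whose arguments are all entities are matched first; matched events
then serve as candidate arguments for higher-order patterns, whose
sub-event node must map onto the trigger token of an already-extracted
event of *any* type (typing the sub-event is left to the pattern's
provenance, and the produced event records the actual matched type).
Because graph matching itself is independent of the candidate pool, the
engine matches each higher-order pattern once and iterates only the
combination step until no new candidate appears (`max_rounds = 10` caps
pathological oscillation; reaching the cap logs a warning and returns the
partial output).

Candidates are deduplicated by recursive structural equality. A structure
produced by several patterns keeps all its (pattern, distance) producers and
is *valid* under a threshold assignment when any producer passes its
pattern's threshold and all sub-event arguments are recursively valid —
this makes cached candidates at the maximal threshold exactly equivalent to
fresh extraction at lower thresholds, the efficiency contract the threshold
learners rely on (and itself a tested property).

Reported events are the *maximal* valid candidates: a candidate is dropped
if another valid candidate with the same type and trigger carries a
superset of its arguments, recursively — an individual-path pattern's
partial event is folded into the union pattern's full event. Without this
consolidation, partial views would count as false positives against their
own training annotation. Pattern statistics credit a pattern with the
consolidated representative of each of its candidates, so individual-path
patterns share credit for the full events they support.

Strict evaluation considers two events equal iff type, trigger token set,
and role-labeled targets agree recursively; precision with an empty
prediction set is defined as 0 (which matters when ranking never-firing
patterns).

## Pattern set optimization

*Precision filtering* ranks every pattern by `n_correct / n_total` over an
end-to-end extraction and removes those below `min_precision = 0.25` (the
preserve-above-a-quarter criterion), iterating to a fixed point because a
removal can starve higher-order patterns downstream.

*Per-pattern thresholds.* Lower-order patterns are tuned by explicit scan
over integer ranges (default `[0, 12]`): a candidate value is accepted only
if training corrects strictly increase at equal-or-better precision, and a
held-out set shows no decrease in either (the validation criterion is
unspecified upstream; we require no degradation, and keep the smallest
qualifying value — a strictness bias). Higher-order patterns cannot be
assessed individually, so a genetic algorithm assigns their thresholds
jointly (default range `[0, 6]`, population 100, 100 generations), with
fitness the F-score of the whole set under the fixed lower-order
thresholds. GA internals are standard and configurable: tournament
selection of size 2, uniform crossover at 0.9, per-gene uniform mutation at
0.1, elitism of 1, seeded and bit-reproducible.

*ERM elimination.* The objective `f(P) = E(P, G) + lambda * C_P` balances
prediction errors `E` (wrong plus missed events) against total redundancy
`C_P`, the summed fraction of non-essential nodes per pattern. Greedy
backward elimination removes, per iteration, the pattern whose removal
reduces `f` the most, stopping when no strict reduction remains (ties by
smallest pattern id). The objective sequence is strictly decreasing, hence
termination. Candidates are extracted once and re-filtered per subset; the
equivalence to full re-evaluation is tested. `lambda` on the scale of the
unit weights is meaningfully 0–10; values of 3 and 6 reproduce the
regularization trade-off in the tests (a redundant verbose duplicate is kept
at `lambda = 0` and eliminated at `lambda = 6`).

## The distributional similarity model

Lexical variation ("crucial" vs "critical") is supported by a thesaurus
built from dependency contexts: each lemma/POS key gets a sparse vector over
features like `toxicity→amod` (governor side) and `severe←amod` (dependent
side). Values are ratio-form pointwise mutual information
`F_c(w) N / (F(w) F(c))` — the printed source formula is typographically
garbled, and the stated `lambda mi / (1 + lambda mi)` scaling with
`lambda = 0.01` only makes sense for unbounded ratios, so the ratio form is
the default and a log form (floored at zero) is a config switch —
discounted by Lin's factor
`F_c(w)/(F_c(w)+1) * min(F(w),F(c))/(min(F(w),F(c))+1)`, then scaled into
`[0, 1)`. Contexts seen at most `min_context_freq = 5` times are dropped.
Similarity is the cosine; `top_m_similar` breaks ties lexicographically.
During matching, `P*+L+DSM` additionally accepts a sentence lemma appearing
among the top-M neighbours of the pattern lemma; generative expansion
instead emits pattern copies with one substitution each. The model
faithfully reproduces the known antonym failure mode: words with identical
context distributions (increase/decrease) are mutual nearest neighbours.

## The synthetic world

`generate_event_corpus` builds matched train/test document pairs over a toy
vocabulary: one planted event complex per sentence — flat (one or two
entity arguments), singly nested (a regulation with an event Theme and an
entity Cause), or a chain of three events — with fixed per-type trigger
lemmas and role edge labels, plus uniquely-lemmatized filler tokens attached
as leaves so they never contaminate induced paths. Defaults (12 documents,
3–6 filler tokens, depth distribution 0.6/0.3/0.1, 35% two-argument flat
events) are chosen as a plausible miniature of shared-task annotation
densities; nothing in the generator is tuned against test outcomes.

Test copies are perturbed per mutually-exclusive channel with the exact
matching cost recorded: a label swap costs `w_l`, a direction flip `w_d`, an
interposed path node `w_s`, and a modifier inserted on the *training* side
costs `w_n / |V_r|`, recoverable only with node skipping (these events'
triggers are renamed so compact patterns from clean documents cannot match
them — otherwise the recorded cost would not be the minimal one). Costs are
recorded for flat-event documents, where the event's own matching cost is
the whole story; in nested documents a perturbed child additionally gates
its ancestors.

What a green test does and does not establish: the generator's sentences
are small trees with template-fixed argument labels and globally unique
filler lemmas, so exact matching is unambiguous by construction. Real parse
graphs bring parser errors, shared triggers across events, long paths and
lexical collisions; results here validate the machinery (distances,
search, learning dynamics), not corpus-level F-scores, which are explicitly
out of scope without the shared-task data.

## A worked run

```{r example, eval = FALSE}
we <- worked_example()
doc <- anonymize_entities(we$doc)
patterns <- dedup_patterns(induce_patterns(doc))
length(patterns)                       # 7: five Positive_regulation + two sub-event patterns
events <- finalize_events(extract_events(doc, patterns, thresholds = 0))
evaluate_strict(events, doc)           # tp = 3, F = 1
```

## Known limitations

* The per-edge alignment rule is this package's concretization; other ASM
  implementations may price multi-hop alignments differently.
* Multi-token entities collapse to a head token chosen as the token whose
  governor leaves the span (ties: rightmost); other conventions exist.
* One candidate event is emitted per combination of sub-events sharing a
  trigger token; emitting a single merged event per trigger is a defensible
  alternative we did not take.
* The official shared-task evaluator's approximate span/recursive matching
  is not implemented; evaluation here is strict.
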