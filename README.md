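# asmevents

Biomedical event extraction by approximate subgraph matching (ASM), in R.

Biomedical events are typed interactions — Binding, Phosphorylation,
Positive_regulation — anchored to a trigger word, with role-labeled
arguments (Theme, Cause) that may be annotated entities or other events.
`asmevents` learns dependency-graph patterns from standoff-annotated
training text (BioNLP shared-task `.txt`/`.a1`/`.a2` plus per-sentence
dependency parses), matches them to new sentences under a tolerance for
syntactic variation, and assembles nested events bottom-up.

The core is the weighted four-component subgraph distance. A pattern graph
G_r = (V_r, E_r) approximately matches a subgraph of a sentence graph G_s
through an injective mapping f when

    subgraphDist_f(G_r, G_s) = w_s·structDist + w_l·labelDist
                             + w_d·directionalityDist + w_n·nodeDist  ≤  t

where the components price, per pattern edge, extra path length, edge-label
mismatch, and orientation mismatch in the sentence, and
`nodeDist = |skipped|/|V_r|` prices skipped non-essential pattern nodes
(trigger and argument nodes are never skippable). Around that core the
package provides:

* **corpus I/O** — standoff + dependency-parse readers/writers, relaxed POS
  tags, entity anonymization (`read_standoff_document`,
  `anonymize_entities`, `write_a2`);
* **pattern induction** — shortest-path, path-union and all-paths patterns
  with role bindings, plus isomorphism deduplication (`induce_patterns`,
  `dedup_patterns`, `write_pattern_store`);
* **matching** — `find_matches` (branch-and-bound, exact) with
  `brute_force_matches` as the test oracle, `P*+L` and DSM-backed node
  matching policies;
* **event engine** — iterative bottom-up extraction of nested events,
  cached-candidate re-filtering, strict evaluation (`extract_events`,
  `filter_candidates`, `evaluate_strict`);
* **optimization** — per-pattern precision filtering, explicit + genetic
  threshold learning, and empirical-risk-minimization backward elimination
  (`precision_filter`, `learn_lower_thresholds`, `ga_optimize_thresholds`,
  `erm_optimize`);
* **distributional similarity** — a discounted, scaled PMI thesaurus over
  dependency contexts (`build_dsm`, `top_m_similar`, `expand_patterns`);
* **synthetic fixtures** — a worked one-sentence example and seeded
  corpus/DSM generators with perturbations of known matching cost
  (`worked_example`, `generate_event_corpus`, `generate_dsm_corpus`).

## Worked example

The bundled fixture reproduces the canonical induction example: one
sentence in which a Positive_regulation (trigger "lead", token 20) takes a
Phosphorylation sub-event as Theme and a Binding sub-event as Cause, with
two shortest paths connecting "lead" and "ligation".

```r
library(asmevents)

we  <- worked_example()
doc <- anonymize_entities(we$doc)

pats <- dedup_patterns(induce_patterns(doc))
purrr::keep(pats, ~ .x$event_type == "Positive_regulation")[[4]]
#> <event_pattern PMC-1134658_p004 [Positive_regulation] t=NA>
#>  bindings: Trigger:lead-20/VBP Theme:phosphorylation-23/NN(Phosphorylation) Cause:ligation-6/NN(Binding)
#>  edges: prep_to(lead-20/VBP, phosphorylation-23/NN) nsubj(lead-20/VBP, ligation-6/NN)

events <- finalize_events(extract_events(doc, pats, thresholds = 0))
evaluate_strict(events, doc)
#> # A tibble: 1 × 6
#>      tp    fp    fn recall precision f_score
#>   <int> <int> <int>  <dbl>     <dbl>   <dbl>
#> 1     3     0     0      1         1       1
```

Five distinct Positive_regulation patterns are induced (two path unions and
three individual paths); matching them back at threshold 0 recovers exactly
the three annotated events, nesting included.

A command-line front end wrapping these functions lives at
`inst/cli/asmevent.R` (`induce`, `extract`, `eval`, `simulate`,
`dsm-build`, `dsm-query`).

## Acceptance script

`scripts/acceptance.R` exercises the full pipeline from scratch: it builds
the worked example and a seeded synthetic corpus, induces and deduplicates
patterns, learns lower-order thresholds, runs the genetic algorithm for the
higher-order ones, re-filters cached candidates, scores extraction
strictly, and applies precision filtering — then writes its JSON report.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The methods vignette (`vignettes/asmevents-methods.Rmd`) documents the
model, the alignment rule, the optimization algorithms, the synthetic
world's assumptions, and known limitations.
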