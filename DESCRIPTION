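Package: asmevents
Title: Approximate Subgraph Matching for Biomedical Event Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts typed, possibly nested biomedical events (e.g. Binding,
    Phosphorylation, Positive_regulation) from dependency-parsed text by
    approximate subgraph matching. Dependency-graph patterns are induced from
    standoff-annotated training sentences (shortest-path, path-union and
    all-paths variants), matched to new sentences under a weighted
    four-component subgraph distance (structure, edge label, edge direction,
    skipped-node penalty), and assembled bottom-up into nested events.
    Pattern sets are optimized by precision filtering, per-pattern distance
    threshold learning (explicit search plus a genetic algorithm), and
    empirical-risk-minimization backward elimination; an optional
    distributional similarity model built from discounted, scaled pointwise
    mutual information over dependency contexts supports lexical variation
    during node matching. Includes generators for synthetic standoff corpora
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    tibble,
    dplyr,
    purrr,
    rlang,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
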