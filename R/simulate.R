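#' The worked pattern-induction example
#'
#' Builds the canonical one-sentence document in which a Positive_regulation
#' event (trigger "lead", token 20) takes a Phosphorylation sub-event
#' (trigger "phosphorylation", token 23) as Theme and a Binding sub-event
#' (trigger "ligation", token 6) as Cause. The dependency graph contains the
#' three decisive edges `nsubj(lead-20, ligation-6)`,
#' `rcmod(ligation-6, lead-20)` and `prep_to(lead-20, phosphorylation-23)`
#' (so two shortest paths connect "lead" and "ligation"), the sub-events'
#' entity arguments, and inert filler tokens attached as leaves so they
#' never lie on induced paths. Five distinct Positive_regulation patterns
#' are inferred from this single example: two path unions and three
#' individual paths.
#'
#' @return list with elements `doc` (the raw [standoff_document()]) and
#'   `expected_patterns` (the five reference patterns, ids E1a..E1e).
#' @export
worked_example <- function() {
  surf <- c("These", "results", "suggest", "that", "CD3", "ligation", "and",
            "costimulation", "of", "resting", "T", "cells", "can", "rapidly",
            "and", "transiently", "as", "shown", "here", "lead", "directly",
            "to", "phosphorylation", "of", "IkBa")
  pos <- c("DT", "NNS", "VBP", "IN", "NN", "NN", "CC", "NN", "IN", "VBG",
           "NN", "NNS", "MD", "RB", "CC", "RB", "IN", "VBN", "RB", "VBP",
           "RB", "TO", "NN", "IN", "NN")
  lemma <- tolower(surf)
  lemma[2] <- "result"; lemma[12] <- "cell"; lemma[18] <- "show"
  tokens <- token_table(seq_along(surf), surf, lemma, pos)
  core <- edge_table(
    governor = c(20L, 6L, 20L, 6L, 23L),
    dependent = c(6L, 20L, 23L, 5L, 25L),
    label = c("nsubj", "rcmod", "prep_to", "nn", "prep_of"))
  filler_dep <- c(1L, 2L, 3L, 4L, 7L, 8L, 9L, 10L, 11L, 12L,
                  13L, 14L, 15L, 16L, 17L, 18L, 19L, 21L, 22L, 24L)
  filler_gov <- c(6L, 6L, 6L, 6L, 6L, 6L, 6L, 6L, 6L, 6L,
                  20L, 20L, 20L, 20L, 20L, 20L, 20L, 20L, 20L, 23L)
  filler_lab <- c("det", "dep", "dep2", "mark", "cc", "conj", "prep", "amod",
                  "nn2", "dep3", "aux", "advmod", "cc2", "advmod2", "mark2",
                  "dep4", "advmod3", "advmod4", "aux2", "prep2")
  edges <- bind_rows(core, edge_table(filler_gov, filler_dep, filler_lab))
  g <- sentence_graph(tokens, edges, "s1")
  text <- paste(surf, collapse = " ")
  spans <- token_spans(text, surf, 1L)
  ent <- tibble(
    id = c("T1", "T2"), type = c("Protein", "Protein"),
    char_start = spans$char_start[c(5, 25)] - 1L,
    char_end = spans$char_end[c(5, 25)] - 1L,
    sentence = "s1", head_token = c(5L, 25L), tokens = list(5L, 25L))
  events <- list(
    E1 = list(id = "E1", type = "Positive_regulation", sentence = "s1",
              trigger_tokens = 20L,
              args = tibble(role = c("Theme", "Cause"),
                            target = c("E3", "E2"))),
    E2 = list(id = "E2", type = "Binding", sentence = "s1",
              trigger_tokens = 6L,
              args = tibble(role = "Theme", target = "T1")),
    E3 = list(id = "E3", type = "Phosphorylation", sentence = "s1",
              trigger_tokens = 23L,
              args = tibble(role = "Theme", target = "T2")))
  doc <- standoff_document("PMC-1134658", text, list(g), ent, events)

  node_sub <- function(idx) tokens[tokens$index %in% idx, ]
  bind <- function(roles, nodes, kinds, subtypes) {
    tibble(node = nodes, role = roles, kind = kinds, subevent_type = subtypes)
  }
  e_nsubj <- edge_table(20L, 6L, "nsubj")
  e_rcmod <- edge_table(6L, 20L, "rcmod")
  e_prep <- edge_table(20L, 23L, "prep_to")
  trig_b <- bind("Trigger", 20L, "trigger", "")
  theme_b <- bind("Theme", 23L, "event", "Phosphorylation")
  cause_b <- bind("Cause", 6L, "event", "Binding")
  expected <- list(
    event_pattern("E1a", "Positive_regulation", node_sub(c(6, 20, 23)),
                  bind_rows(e_nsubj, e_prep),
                  bind_rows(trig_b, theme_b, cause_b)),
    event_pattern("E1b", "Positive_regulation", node_sub(c(6, 20, 23)),
                  bind_rows(e_rcmod, e_prep),
                  bind_rows(trig_b, theme_b, cause_b)),
    event_pattern("E1c", "Positive_regulation", node_sub(c(20, 23)),
                  e_prep, bind_rows(trig_b, theme_b)),
    event_pattern("E1d", "Positive_regulation", node_sub(c(6, 20)),
                  e_nsubj, bind_rows(trig_b, cause_b)),
    event_pattern("E1e", "Positive_regulation", node_sub(c(6, 20)),
                  e_rcmod, bind_rows(trig_b, cause_b)))
  names(expected) <- c("E1a", "E1b", "E1c", "E1d", "E1e")
  list(doc = doc, expected_patterns = expected)
}

#' Specification for a synthetic event corpus
#'
#' States the simulated world: how many documents, how much inert filler per
#' sentence, the distribution of event nesting depths, the per-channel
#' perturbation rates applied to the test copies, and the rate of
#' distractor ("junk") sentences that support a junk pattern. Perturbation
#' channels are mutually exclusive per event so each recorded matching cost
#' is exact.
#'
#' @param n_docs documents per side (train and test).
#' @param n_filler integer range of filler tokens per sentence.
#' @param depth_probs probabilities of event nesting depth 1 (flat), 2
#'   (one regulation layer) and 3 (a chain of three events).
#' @param two_arg_prob probability that a flat event takes two entity
#'   arguments instead of one.
#' @param flat_types which of the three flat event templates to draw from
#'   (default all three); restricting to one makes the induced pattern
#'   inventory deterministic.
#' @param perturb named numeric rates in `[0,1]` for channels
#'   `label_swap`, `direction_flip`, `node_insertion`, `modifier_insertion`.
#' @param junk_rate probability of appending a distractor sentence with an
#'   annotated entity but no event.
#' @param perturb_reg rate of label-swapping the regulation layer's Theme
#'   edge in the test copy of nested sentences (cost `w_l` for the parent
#'   event; not tracked in `costs`, used to make higher-order threshold
#'   learning non-trivial).
#' @param decoy_modifier add a constant `advmod` leaf to flat-event triggers
#'   (supports redundant-pattern fixtures).
#' @param weights [distance_weights()] used to price perturbation costs.
#' @param seed mandatory RNG seed.
#' @return object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_docs = 12L, n_filler = 3:6,
                        depth_probs = c(0.6, 0.3, 0.1), two_arg_prob = 0.35,
                        flat_types = 1:3,
                        perturb = c(label_swap = 0, direction_flip = 0,
                                    node_insertion = 0,
                                    modifier_insertion = 0),
                        junk_rate = 0, decoy_modifier = FALSE,
                        perturb_reg = 0, weights = distance_weights(), seed) {
  if (missing(seed)) abort("corpus_spec requires a seed")
  pr <- c(label_swap = 0, direction_flip = 0, node_insertion = 0,
          modifier_insertion = 0)
  pr[names(perturb)] <- perturb
  if (any(pr < 0 | pr > 1)) abort("perturbation rates must be in [0,1]")
  if (sum(pr) > 1) abort("perturbation rates must sum to at most 1")
  structure(list(n_docs = as.integer(n_docs), n_filler = n_filler,
                 depth_probs = depth_probs / sum(depth_probs),
                 two_arg_prob = two_arg_prob,
                 flat_types = as.integer(flat_types), perturb = pr,
                 junk_rate = junk_rate, decoy_modifier = decoy_modifier,
                 perturb_reg = perturb_reg,
                 weights = weights, seed = as.integer(seed)),
            class = "corpus_spec")
}

# fixed toy templates: trigger lemma and argument edge labels per event type
event_templates <- function() {
  list(
    flat = list(
      list(type = "Phosphorylation", trigger = "phosphorylation", pos = "NN",
           theme_label = "prep_of", theme2_label = "prep_at"),
      list(type = "Gene_expression", trigger = "expression", pos = "NN",
           theme_label = "prep_of", theme2_label = "prep_in"),
      list(type = "Localization", trigger = "translocation", pos = "NN",
           theme_label = "prep_of", theme2_label = "prep_to")
    ),
    reg = list(type = "Positive_regulation", trigger = "induce", pos = "VBZ",
               theme_label = "dobj", cause_label = "nsubj"),
    chain = list(type = "Regulation", trigger = "block", pos = "VBZ",
                 theme_label = "dobj")
  )
}

#' Generate a synthetic annotated event corpus
#'
#' Builds matched train/test document pairs over a toy vocabulary: each
#' sentence contains a planted event (flat, singly nested, or a chain of
#' three events) whose triggers and role-bearing dependency labels follow
#' fixed per-type templates, plus uniquely-lemmatized filler tokens attached
#' as leaves. Test copies are perturbed per channel with the exact matching
#' cost of each perturbation recorded, so the minimal distance at which
#' every planted event can be recovered is known by construction:
#' \itemize{
#'   \item `label_swap` rewrites one argument edge label (cost `w_l`);
#'   \item `direction_flip` reverses it (cost `w_d`);
#'   \item `node_insertion` interposes a fresh token on it, keeping the
#'     original label on the first hop (cost `w_s`);
#'   \item `modifier_insertion` interposes the token in the \emph{training}
#'     copy instead, so the induced pattern carries a non-essential node the
#'     test sentence lacks (cost `w_n / |V_r|`, recoverable only with node
#'     skipping).
#' }
#' Everything is deterministic given `spec$seed`.
#'
#' @param spec a [corpus_spec()].
#' @return list with `train` and `test` (anonymized document lists), `gold`
#'   (test-side gold signatures), `costs` (tibble: doc, signature, channel,
#'   cost, pattern node count; recorded for flat-event documents, where the
#'   perturbation cost is exactly the event's matching cost — in nested
#'   documents the perturbed flat event additionally gates its ancestors),
#'   and `junk_pattern` (an [event_pattern()] firing only on distractor
#'   sentences, or `NULL`).
#' @export
generate_event_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  tpl <- event_templates()
  w <- spec$weights
  with_seed(spec$seed, {
    train <- list(); test <- list()
    costs <- tibble(doc = character(), signature = character(),
                    channel = character(), cost = numeric(),
                    pattern_nodes = integer())
    any_junk <- FALSE
    for (d in seq_len(spec$n_docs)) {
      doc_id <- sprintf("d%03d", d)
      b <- build_document(doc_id, spec, tpl)
      train[[d]] <- b$train; test[[d]] <- b$test
      costs <- bind_rows(costs, b$costs)
      any_junk <- any_junk || b$had_junk
    }
    junk <- if (any_junk || spec$junk_rate > 0) junk_pattern() else NULL
    train <- lapply(train, anonymize_entities)
    test <- lapply(test, anonymize_entities)
    list(train = train, test = test,
         gold = unique(unlist(lapply(test, gold_signatures))),
         costs = costs, junk_pattern = junk)
  })
}

junk_pattern <- function() {
  nodes <- token_table(index = 1:2, surface = c("level", "Protein"),
                       lemma = c("level", "Protein"), pos = c("NN", "NN"),
                       entity_type = c("", "Protein"))
  event_pattern("junk_level", "Gene_expression", nodes,
                edge_table(1L, 2L, "prep_of"),
                tibble(node = 1:2, role = c("Trigger", "Theme"),
                       kind = c("trigger", "entity"), subevent_type = c("", "")),
                threshold = 0,
                provenance = list(doc = "junk", sentence = "", event = ""))
}

# one train/test document pair; mutable token accumulator style.
build_document <- function(doc_id, spec, tpl) {
  sent <- new_sentence_builder()
  ent_n <- 0L; ev_n <- 0L
  entities <- list(); events <- list()
  new_entity <- function(tok_idx) {
    ent_n <<- ent_n + 1L
    id <- paste0("T", ent_n)
    entities[[id]] <<- list(id = id, token = tok_idx)
    id
  }
  new_event <- function(type, trig, args) {
    ev_n <<- ev_n + 1L
    id <- paste0("E", ev_n)
    events[[id]] <<- list(id = id, type = type, trigger = trig, args = args)
    id
  }
  plant_flat <- function() {
    t <- if (length(spec$flat_types) == 1) spec$flat_types else
      sample(spec$flat_types, 1)
    tmpl <- tpl$flat[[t]]
    trig <- sent$add(tmpl$trigger, tmpl$pos)
    ent1 <- sent$add(paste0("GENE", ent_n + 1L), "NN")
    sent$edge(trig, ent1, tmpl$theme_label)
    args <- tibble(role = "Theme", target = new_entity(ent1))
    if (stats::runif(1) < spec$two_arg_prob) {
      ent2 <- sent$add(paste0("GENE", ent_n + 1L), "NN")
      sent$edge(trig, ent2, tmpl$theme2_label)
      args <- bind_rows(args, tibble(role = "Theme2",
                                     target = new_entity(ent2)))
    }
    if (spec$decoy_modifier) sent$edge(trig, sent$add("notably", "RB"), "advmod")
    list(id = new_event(tmpl$type, trig, args), trigger = trig,
         theme_edge = 1L)  # first edge added is the Theme edge
  }
  plant_reg <- function(child) {
    trig <- sent$add(tpl$reg$trigger, tpl$reg$pos)
    sent$edge(trig, child$trigger, tpl$reg$theme_label)
    ce <- sent$add(paste0("GENE", ent_n + 1L), "NN")
    sent$edge(trig, ce, tpl$reg$cause_label)
    args <- tibble(role = c("Theme", "Cause"),
                   target = c(child$id, new_entity(ce)))
    list(id = new_event(tpl$reg$type, trig, args), trigger = trig)
  }
  plant_chain <- function(mid) {
    trig <- sent$add(tpl$chain$trigger, tpl$chain$pos)
    sent$edge(trig, mid$trigger, tpl$chain$theme_label)
    args <- tibble(role = "Theme", target = mid$id)
    list(id = new_event(tpl$chain$type, trig, args), trigger = trig)
  }

  depth <- sample(1:3, 1, prob = spec$depth_probs)
  flat <- plant_flat()
  top <- flat
  if (depth >= 2) top <- plant_reg(flat)
  if (depth >= 3) top <- plant_chain(top)
  n_fill <- if (length(spec$n_filler) == 1) spec$n_filler else
    sample(spec$n_filler, 1)
  for (i in seq_len(n_fill)) sent$filler()
  sentences <- list(sent$freeze())

  had_junk <- FALSE
  if (stats::runif(1) < spec$junk_rate) {
    js <- new_sentence_builder()
    lvl <- js$add("level", "NN")
    je <- js$add(paste0("GENE", ent_n + 1L), "NN")
    js$edge(lvl, je, "prep_of")
    new_entity_junk <- new_entity(je)
    entities[[new_entity_junk]]$sentence <- 2L
    for (i in seq_len(3)) js$filler()
    sentences[[2]] <- js$freeze()
    had_junk <- TRUE
  }

  assemble <- function(sentence_tables, doc_suffix) {
    graphs <- lapply(seq_along(sentence_tables), function(i) {
      sentence_graph(sentence_tables[[i]]$tokens, sentence_tables[[i]]$edges,
                     paste0("s", i))
    })
    text_lines <- vapply(graphs, function(g) {
      paste(g$tokens$surface, collapse = " ")
    }, character(1))
    text <- paste(text_lines, collapse = "\n")
    sent_start <- c(1L, head(cumsum(nchar(text_lines) + 1L), -1) + 1L)
    ent_tab <- empty_entities()
    for (e in entities) {
      si <- e$sentence %||% 1L
      sp <- token_spans(text_lines[si], graphs[[si]]$tokens$surface,
                        sent_start[si])
      k <- match(e$token, graphs[[si]]$tokens$index)
      ent_tab <- bind_rows(ent_tab, tibble(
        id = e$id, type = "Protein",
        char_start = sp$char_start[k] - 1L, char_end = sp$char_end[k] - 1L,
        sentence = paste0("s", si), head_token = e$token,
        tokens = list(e$token)))
    }
    ev_list <- lapply(events, function(ev) {
      list(id = ev$id, type = ev$type, sentence = "s1",
           trigger_tokens = ev$trigger, args = ev$args)
    })
    standoff_document(paste0(doc_id, doc_suffix), text, graphs, ent_tab,
                      ev_list)
  }

  train_doc <- assemble(sentences, "")

  # perturb the test copy of the flat event's Theme edge (flat-only so the
  # recorded cost is exactly the event's own matching cost)
  costs <- tibble(doc = character(), signature = character(),
                  channel = character(), cost = numeric(),
                  pattern_nodes = integer())
  u <- stats::runif(1)
  cum <- cumsum(spec$perturb)
  channel <- if (u < cum[1]) "label_swap" else if (u < cum[2]) {
    "direction_flip"
  } else if (u < cum[3]) "node_insertion" else if (u < cum[4]) {
    "modifier_insertion"
  } else "none"
  s1 <- sentences[[1]]
  test_s1 <- s1
  # the flat event's Theme edge is always the first edge recorded
  te <- 1L
  if (channel == "label_swap") {
    test_s1$edges$label[te] <- paste0("swp_", test_s1$edges$label[te])
  } else if (channel == "direction_flip") {
    gv <- test_s1$edges$governor[te]
    test_s1$edges$governor[te] <- test_s1$edges$dependent[te]
    test_s1$edges$dependent[te] <- gv
  } else if (channel == "node_insertion") {
    mid <- max(test_s1$tokens$index) + 1L
    test_s1$tokens <- bind_rows(
      test_s1$tokens,
      token_table(mid, paste0("mid", sample(1e6L, 1)), pos = "NN"))
    ent_node <- test_s1$edges$dependent[te]
    test_s1$edges$dependent[te] <- mid
    test_s1$edges <- bind_rows(test_s1$edges,
                               edge_table(mid, ent_node, "dep"))
  } else if (channel == "modifier_insertion") {
    # rename the trigger so compact patterns from clean documents of the
    # same type cannot match; only the verbose pattern (with the inserted
    # non-essential node) applies, and only by skipping that node.
    trig_tok <- s1$edges$governor[te]
    k <- match(trig_tok, s1$tokens$index)
    s1$tokens$lemma[k] <- paste0(s1$tokens$lemma[k], "like")
    s1$tokens$surface[k] <- s1$tokens$lemma[k]
    test_s1 <- s1
    # insert in the TRAIN copy: induced pattern gains a non-essential node
    mid <- max(s1$tokens$index) + 1L
    tr_s1 <- s1
    tr_s1$tokens <- bind_rows(
      tr_s1$tokens,
      token_table(mid, paste0("mid", sample(1e6L, 1)), pos = "NN"))
    ent_node <- tr_s1$edges$dependent[te]
    tr_s1$edges$dependent[te] <- mid
    tr_s1$edges <- bind_rows(tr_s1$edges, edge_table(mid, ent_node, "dep"))
    sentences[[1]] <- tr_s1
    train_doc <- assemble(sentences, "")
  }
  test_sentences <- sentences
  test_sentences[[1]] <- if (channel == "modifier_insertion") s1 else test_s1
  if (depth >= 2 && stats::runif(1) < spec$perturb_reg) {
    ts <- test_sentences[[1]]
    k <- which(ts$edges$label == tpl$reg$theme_label)
    if (length(k)) {
      ts$edges$label[k[1]] <- paste0("swp_", ts$edges$label[k[1]])
      test_sentences[[1]] <- ts
    }
  }
  test_doc <- assemble(test_sentences, "t")

  if (depth == 1) {
    flat_ev <- events[[flat$id]]
    # signature of the flat event in the (anonymized) test document
    sig <- {
      adoc <- anonymize_entities(test_doc)
      gold_signatures(adoc)[match(flat$id, names(adoc$events))]
    }
    w <- spec$weights
    # union-pattern node count: trigger + args (+ inserted path node)
    pat_nodes <- 1L + nrow(flat_ev$args) +
      (channel == "modifier_insertion")
    cost <- switch(channel,
      none = 0, label_swap = w$w_l, direction_flip = w$w_d,
      node_insertion = w$w_s,
      modifier_insertion = w$w_n / pat_nodes)
    costs <- bind_rows(costs, tibble(
      doc = test_doc$doc_id, signature = sig, channel = channel,
      cost = cost, pattern_nodes = pat_nodes))
  }
  list(train = train_doc, test = test_doc, costs = costs, had_junk = had_junk)
}

new_sentence_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$tokens <- token_table(integer(0), character(0))
  env$edges <- edge_table()
  env$fill_n <- 0L
  add <- function(lemma, pos, surface = lemma, entity_type = "") {
    idx <- nrow(env$tokens) + 1L
    env$tokens <- bind_rows(env$tokens, token_table(
      idx, surface = surface, lemma = lemma, pos = pos,
      entity_type = entity_type))
    idx
  }
  edge <- function(gov, dep, label) {
    env$edges <- bind_rows(env$edges, edge_table(gov, dep, label))
    invisible(NULL)
  }
  filler <- function() {
    env$fill_n <- env$fill_n + 1L
    lem <- paste0("fill", env$fill_n, "x", sample(1000L, 1))
    anchor <- sample(env$tokens$index, 1)
    idx <- add(lem, "NN")
    lab <- sample(c("det", "amod", "advmod", "aux", "dep", "cc"), 1)
    # avoid duplicate triples on the same anchor
    while (any(env$edges$governor == anchor & env$edges$dependent == idx &
               env$edges$label == lab)) {
      lab <- paste0(lab, "x")
    }
    edge(anchor, idx, lab)
  }
  freeze <- function() list(tokens = env$tokens, edges = env$edges)
  list(add = add, edge = edge, filler = filler, freeze = freeze)
}

#' Specification for a synthetic DSM corpus
#'
#' Words are assigned to context-distribution classes; all words of one
#' class (including designated antonym pairs such as increase/decrease) are
#' emitted with identical dependency-context distributions, plus optional
#' shared-pool noise contexts.
#'
#' @param classes list of character vectors, the words of each class.
#' @param contexts_per_class distinct contexts per class.
#' @param reps occurrences of each (word, context) pair (keep above the
#'   model's minimum context frequency).
#' @param noise_rate probability of an extra noise-context occurrence per
#'   emission.
#' @param word_pos POS tag of class words.
#' @param seed mandatory RNG seed.
#' @return object of class `dsm_corpus_spec`.
#' @export
dsm_corpus_spec <- function(classes = list(), contexts_per_class = 4L,
                            reps = 7L, noise_rate = 0.05, word_pos = "JJ",
                            seed) {
  if (missing(seed)) abort("dsm_corpus_spec requires a seed")
  structure(list(classes = classes,
                 contexts_per_class = as.integer(contexts_per_class),
                 reps = as.integer(reps), noise_rate = noise_rate,
                 word_pos = word_pos, seed = as.integer(seed)),
            class = "dsm_corpus_spec")
}

#' Generate a dependency-parsed DSM toy corpus
#'
#' Emits two-token sentences pairing each class word with each of its
#' class's governor contexts, `reps` times, in deterministic seeded order.
#'
#' @param spec a [dsm_corpus_spec()].
#' @return list of [sentence_graph()] (empty for an empty spec).
#' @export
generate_dsm_corpus <- function(spec) {
  stopifnot(inherits(spec, "dsm_corpus_spec"))
  if (!length(spec$classes)) return(list())
  with_seed(spec$seed, {
    out <- list()
    sid <- 0L
    emit <- function(ctx_lemma, rel, word, wpos) {
      sid <<- sid + 1L
      tokens <- token_table(1:2, surface = c(ctx_lemma, word),
                           lemma = c(ctx_lemma, word),
                           pos = c("NN", wpos))
      out[[sid]] <<- sentence_graph(tokens, edge_table(1L, 2L, rel),
                                    paste0("dsm_s", sid))
    }
    for (k in seq_along(spec$classes)) {
      ctxs <- paste0("ctx", k, "_", seq_len(spec$contexts_per_class))
      rel <- paste0("rel", k)
      for (wd in spec$classes[[k]]) {
        for (cx in ctxs) {
          for (r in seq_len(spec$reps)) {
            emit(cx, rel, wd, spec$word_pos)
            if (stats::runif(1) < spec$noise_rate) {
              emit(paste0("noise", sample(6L, 1)), "nmod", wd, spec$word_pos)
            }
          }
        }
      }
    }
    out
  })
}

#' Add a redundant non-essential node to a pattern
#'
#' Produces a verbose variant of a pattern by attaching one extra
#' non-essential leaf node to its trigger. When the corresponding decoy
#' token is present in the corpus (see `decoy_modifier` in [corpus_spec()]),
#' the variant fires on exactly the same sentences as the original but with
#' a strictly higher redundancy, the configuration the ERM optimizer is
#' meant to eliminate.
#'
#' @param p an [event_pattern()].
#' @param lemma,pos,label the decoy node and its attachment.
#' @return the verbose [event_pattern()].
#' @export
add_redundant_node <- function(p, lemma = "notably", pos = "RB",
                               label = "advmod") {
  idx <- max(p$nodes$index) + 1L
  trig <- p$bindings$node[p$bindings$kind == "trigger"][1]
  nodes <- bind_rows(p$nodes, token_table(idx, lemma, lemma, pos))
  edges <- bind_rows(p$edges, edge_table(trig, idx, label))
  event_pattern(paste0(p$pattern_id, "_verbose"), p$event_type, nodes, edges,
                p$bindings, threshold = p$threshold, provenance = p$provenance)
}
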