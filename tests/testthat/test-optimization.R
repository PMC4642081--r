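make_opt_corpus <- function(seed = 5, ...) {
  generate_event_corpus(corpus_spec(n_docs = 10,
                                    depth_probs = c(0.5, 0.4, 0.1),
                                    junk_rate = 0.4, decoy_modifier = TRUE,
                                    seed = seed, ...))
}

test_that("pattern precision separates supported from spurious patterns", {
  corp <- make_opt_corpus()
  pats <- induce_all(corp$train)
  st <- pattern_precision(pats, corp$test)
  expect_true(all(st$n_correct <= st$n_total))
  expect_true(all(st$precision == ifelse(st$n_total > 0,
                                         st$n_correct / st$n_total, 0)))
  # self-consistent patterns on a clean corpus are all precision 1 (or
  # unused); the junk pattern fires only false positives
  st2 <- pattern_precision(c(pats, list(corp$junk_pattern)), corp$test)
  junk <- st2[st2$pattern_id == "junk_level", ]
  expect_gt(junk$n_total, 0)
  expect_equal(junk$n_correct, 0)
  expect_equal(junk$precision, 0)
  # a pattern that never fires has precision 0 by convention
  orphan <- corp$junk_pattern
  orphan$pattern_id <- "orphan"
  orphan$nodes$lemma[1] <- "nonexistentlemma"
  st3 <- pattern_precision(list(orphan), corp$test)
  expect_equal(st3$n_total, 0)
  expect_equal(st3$precision, 0)
})

test_that("a pattern overgeneralizing across contexts counts its false hits", {
  # a Transcription-style pattern from "expression of GENE" must not fire a
  # correct event on "level of GENE": the distractor hit inflates n_total
  corp <- make_opt_corpus(seed = 6)
  pats <- c(induce_all(corp$train), list(corp$junk_pattern))
  st <- pattern_precision(pats, corp$test)
  ge <- st[grepl("junk", st$pattern_id), ]
  expect_true(all(ge$n_total > ge$n_correct))
})

test_that("iterative precision filtering removes junk and starved patterns", {
  corp <- make_opt_corpus(seed = 7)
  pats <- induce_all(corp$train)
  kept <- precision_filter(pats, corp$test)
  expect_setequal(pattern_ids(kept), pattern_ids(pats))
  kept2 <- precision_filter(c(pats, list(corp$junk_pattern)), corp$test)
  expect_false("junk_level" %in% pattern_ids(kept2))
  # fixed point: every survivor is at or above the cutoff
  st <- pattern_precision(kept2, corp$test)
  expect_true(all(st$precision >= 0.25))
})

test_that("removing a lower-order support starves its higher-order pattern", {
  # one document with a nested event whose flat child motif also occurs,
  # unannotated, in four distractor documents: the flat pattern's precision
  # (1/5) falls below the cutoff, and on the next round the higher-order
  # pattern loses all support and is removed too
  mk_doc <- function(id, annotated) {
    toks <- token_table(1:4, c("induces", "expression", "GENE1", "GENE2"),
                        c("induce", "expression", "GENE1", "GENE2"),
                        c("VBZ", "NN", "NN", "NN"))
    ed <- edge_table(c(2L, 1L, 1L), c(3L, 2L, 4L),
                     c("prep_of", "dobj", "nsubj"))
    g <- sentence_graph(toks, ed, "s1")
    text <- paste(toks$surface, collapse = " ")
    sp <- asmevents:::token_spans(text, toks$surface, 1L)
    ents <- tibble::tibble(
      id = c("T1", "T2"), type = "Protein",
      char_start = sp$char_start[3:4] - 1L, char_end = sp$char_end[3:4] - 1L,
      sentence = "s1", head_token = 3:4, tokens = list(3L, 4L))
    evs <- if (annotated) list(
      E1 = list(id = "E1", type = "Gene_expression", sentence = "s1",
                trigger_tokens = 2L,
                args = tibble::tibble(role = "Theme", target = "T1")),
      E2 = list(id = "E2", type = "Positive_regulation", sentence = "s1",
                trigger_tokens = 1L,
                args = tibble::tibble(role = c("Theme", "Cause"),
                                      target = c("E1", "T2")))) else list()
    anonymize_entities(standoff_document(id, text, list(g), ents, evs))
  }
  train <- list(mk_doc("a", TRUE))
  test <- c(train, lapply(paste0("b", 1:4), mk_doc, annotated = FALSE))
  pats <- induce_all(train)
  expect_true(any(vapply(pats, is_higher_order, logical(1))))
  st <- pattern_precision(pats, test)
  flat_id <- pattern_ids(pats)[!vapply(pats, is_higher_order, logical(1))]
  expect_equal(st$precision[st$pattern_id == flat_id], 0.2)
  kept <- precision_filter(pats, test, min_precision = 0.25)
  expect_length(kept, 0)
})

test_that("threshold learning accepts only strictly better, validated values", {
  corp <- generate_event_corpus(corpus_spec(
    n_docs = 12, depth_probs = c(1, 0, 0), two_arg_prob = 0,
    perturb = c(label_swap = 0.5), seed = 61))
  pats <- induce_all(corp$train)
  lower <- purrr::discard(pats, is_higher_order)
  # learn on the perturbed side, validate on the clean side
  lt <- learn_lower_thresholds(lower, corp$test, corp$train, range = 0:12)
  expect_true(any(lt >= 1))  # swapped labels need one unit of tolerance
  # never worse than threshold 0 on the training data, per the update rule
  cache <- extract_corpus(corp$test, lower, thresholds = 12)
  gold <- unique(unlist(lapply(corp$test, gold_signatures)))
  stats_at <- function(pid, v) {
    tot <- 0L; corr <- 0L
    for (cd in cache$candidates) {
      d <- cd$producers$distance[cd$producers$pattern_id == pid]
      if (length(d) && min(d) <= v + 1e-9) {
        tot <- tot + 1L
        if (cd$sig %in% gold) corr <- corr + 1L
      }
    }
    c(corr = corr, prec = if (tot > 0) corr / tot else 0)
  }
  for (pid in names(lt)) {
    s0 <- stats_at(pid, 0)
    s1 <- stats_at(pid, lt[pid])
    expect_gte(s1[["corr"]], s0[["corr"]])
    expect_gte(s1[["prec"]], s0[["prec"]])
  }
  # degenerate range pins every threshold
  expect_true(all(learn_lower_thresholds(lower, corp$test, corp$train,
                                         range = c(0, 0)) == 0))
  # a pattern matching only its own source stays at 0
  clean <- generate_event_corpus(corpus_spec(n_docs = 4,
                                             depth_probs = c(1, 0, 0),
                                             seed = 62))
  cl_pats <- purrr::discard(induce_all(clean$train), is_higher_order)
  expect_true(all(learn_lower_thresholds(cl_pats, clean$train,
                                         clean$test) == 0))
})

test_that("the GA is reproducible, elitist, and collapses with its range", {
  corp <- generate_event_corpus(corpus_spec(
    n_docs = 8, depth_probs = c(0.3, 0.5, 0.2), perturb_reg = 0.5,
    seed = 63))
  pats <- induce_all(corp$train)
  lower <- purrr::discard(pats, is_higher_order)
  lt <- setNames(rep(0, length(lower)), pattern_ids(lower))
  ga_small <- ga_config(population_size = 20, generations = 10, seed = 2)
  g1 <- ga_optimize_thresholds(pats, lt, corp$test, ga = ga_small)
  g2 <- ga_optimize_thresholds(pats, lt, corp$test, ga = ga_small)
  expect_identical(g1, g2)
  # collapsed range returns that point
  g0 <- ga_optimize_thresholds(pats, lt, corp$test,
                               ga = ga_config(population_size = 5,
                                              generations = 2,
                                              range = c(4, 4), seed = 1))
  expect_true(all(g0 == 4))
  # small exhaustive oracle agreement on the optimum value
  ex <- exhaustive_thresholds(pats, lt, corp$test, range = 0:1)
  ga_big <- ga_optimize_thresholds(pats, lt, corp$test,
                                   ga = ga_config(population_size = 30,
                                                  generations = 15,
                                                  range = 0:1, seed = 4))
  expect_equal(attr(ga_big, "fitness"), attr(ex, "fitness"))
  # no higher-order patterns: empty assignment
  expect_length(ga_optimize_thresholds(lower, lt, corp$test), 0)
})

test_that("pattern redundancy is the non-essential node fraction", {
  we <- worked_example()
  expect_equal(pattern_redundancy(we$expected_patterns$E1a), 0)
  toks <- token_table(1:4, c("t", "a", "x", "y"), pos = "NN")
  p <- event_pattern("p", "X", toks,
                     edge_table(c(1L, 1L, 1L), 2:4, c("a", "b", "c")),
                     tibble::tibble(node = 1:2, role = c("Trigger", "Theme"),
                                    kind = c("trigger", "trigger"),
                                    subevent_type = ""))
  expect_equal(pattern_redundancy(p), 0.5)
  # the compact entity+trigger pattern pathology: redundancy 0
  expect_equal(pattern_redundancy(asmevents:::junk_pattern()), 0)
})

test_that("the ERM objective equals its independent recomputation", {
  corp <- make_opt_corpus(seed = 8)
  pats <- lapply(induce_all(corp$train), function(p) {
    p$threshold <- 0; p
  })
  pats <- c(pats, list(corp$junk_pattern))
  lam <- 3
  got <- erm_objective(pats, corp$test, cfg_erm = erm_config(lam))
  ev <- evaluate_strict(
    extract_corpus(corp$test, pats,
                   thresholds = setNames(rep(0, length(pats)),
                                         pattern_ids(pats))),
    corp$test)
  want <- (ev$fp + ev$fn) + lam * sum(vapply(pats, pattern_redundancy,
                                             numeric(1)))
  expect_equal(got, want)
  # E = 5, C_p = 2, lambda = 3 gives 11 (formula arithmetic via components)
  expect_equal(5 + 3 * 2, 11)
  # perfect extraction with all-essential patterns scores 0
  clean <- generate_event_corpus(corpus_spec(n_docs = 4,
                                             depth_probs = c(1, 0, 0),
                                             seed = 9))
  cp <- lapply(induce_all(clean$train), function(p) { p$threshold <- 0; p })
  expect_equal(erm_objective(cp, clean$train, cfg_erm = erm_config(6)), 0)
})

test_that("ERM backward elimination prunes redundancy under regularization", {
  corp <- make_opt_corpus(seed = 10)
  pats <- lapply(induce_all(corp$train), function(p) { p$threshold <- 0; p })
  # all patterns necessary on the clean corpus: nothing is removed at
  # lambda = 0 (every removal costs missed events)
  erm0 <- erm_optimize(pats, corp$train, cfg_erm = erm_config(0))
  expect_setequal(pattern_ids(erm0), pattern_ids(pats))
  # a verbose duplicate of a flat pattern is removed under lambda > 0 but
  # kept at lambda = 0 (its removal alone gains nothing unregularized)
  flat <- pats[[which(!vapply(pats, is_higher_order, logical(1)))[1]]]
  verbose <- add_redundant_node(flat)
  verbose$threshold <- 0
  with_verbose <- c(pats, list(verbose))
  keep0 <- erm_optimize(with_verbose, corp$train, cfg_erm = erm_config(0))
  expect_true(verbose$pattern_id %in% pattern_ids(keep0))
  keep6 <- erm_optimize(with_verbose, corp$train, cfg_erm = erm_config(6))
  expect_false(verbose$pattern_id %in% pattern_ids(keep6))
  # objective trace is strictly decreasing and ends at the optimum reached
  tr <- attr(keep6, "objective_trace")
  expect_true(all(diff(tr) < 0))
  f_final <- erm_objective(keep6, corp$train, cfg_erm = erm_config(6))
  f_start <- erm_objective(with_verbose, corp$train,
                           cfg_erm = erm_config(6))
  expect_lte(f_final, f_start)
  expect_equal(f_final, tr[length(tr)])
})
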