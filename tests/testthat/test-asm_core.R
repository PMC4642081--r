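tok1 <- function(surface, pos, lemma = tolower(surface), entity = "") {
  token_table(1L, surface, lemma, pos, entity_type = entity)[1, ]
}

test_that("P*+L node matching collapses inflection but requires the lemma", {
  expect_true(node_match(tok1("phosphorylation", "NN"),
                         tok1("phosphorylations", "NNS",
                              lemma = "phosphorylation")))
  expect_false(node_match(tok1("crucial", "JJ"), tok1("critical", "JJ")))
  expect_true(node_match(tok1("lead", "VBP"), tok1("lead", "VBP")))
  expect_false(node_match(tok1("lead", "VBP"), tok1("lead", "NN")))
  # entity-bound nodes match only entities of the same generic type
  pe <- tok1("Protein", "NN", lemma = "Protein", entity = "Protein")
  se <- tok1("Protein", "NN", lemma = "Protein", entity = "Protein")
  so <- tok1("Organism", "NN", lemma = "Organism", entity = "Organism")
  expect_true(node_match(pe, se))
  expect_false(node_match(pe, so))
  expect_false(node_match(pe, tok1("protein", "NN")))
  expect_false(node_match(tok1("protein", "NN"), se))
})

test_that("DSM-backed matching accepts distributional neighbours", {
  corp <- generate_dsm_corpus(dsm_corpus_spec(
    classes = list(c("crucial", "critical"), c("strong", "weak")),
    noise_rate = 0, seed = 4))
  m <- build_dsm(corp)
  pol <- match_policy("PSL_DSM", dsm_model = m, dsm_top_m = 1)
  expect_true(node_match(tok1("crucial", "JJ"), tok1("critical", "JJ"), pol))
  expect_false(node_match(tok1("crucial", "JJ"), tok1("strong", "JJ"), pol))
  expect_false(node_match(tok1("crucial", "JJ"), tok1("critical", "NN"), pol))
  expect_error(match_policy("PSL_DSM"), "dsm_model")
})

test_that("edge alignment prices label, direction and structural divergence", {
  we <- worked_example()
  g <- anonymize_entities(we$doc)$sentences[[1]]
  # identical edge: all zero
  e <- g$edges[g$edges$label == "prep_to", ]
  m <- asm_mapping(c("20" = 20L, "23" = 23L))
  expect_equal(unname(edge_alignment(e, g, m)), c(0, 0, 0))
  # nsubj pattern edge onto a sentence holding only rcmod(ligation, lead)
  toks <- token_table(1:2, c("lead", "ligation"), pos = c("VBP", "NN"))
  g2 <- sentence_graph(toks, edge_table(2L, 1L, "rcmod"))
  pe <- tibble::tibble(governor = 10L, dependent = 11L, label = "nsubj")
  m2 <- asm_mapping(c("10" = 1L, "11" = 2L))
  expect_equal(unname(edge_alignment(pe, g2, m2)), c(0, 1, 1))
  # images two hops apart with the pattern label on one consistent hop
  toks3 <- token_table(1:3, c("a", "mid", "b"), pos = "NN")
  g3 <- sentence_graph(toks3, edge_table(c(1L, 2L), c(2L, 3L),
                                         c("nsubj", "dep")))
  m3 <- asm_mapping(c("10" = 1L, "11" = 3L))
  expect_equal(unname(edge_alignment(pe, g3, m3)), c(1, 0, 0))
  # disconnected images fail
  g4 <- sentence_graph(toks3, edge_table(1L, 2L, "nsubj"))
  expect_error(edge_alignment(pe, g4, m3), "disconnected")
})

test_that("subgraph distance follows the weighted four-component formula", {
  we <- worked_example()
  doc <- anonymize_entities(we$doc)
  g <- doc$sentences[[1]]
  pats <- induce_patterns(doc)
  for (p in pats) {
    pairs <- setNames(p$nodes$index, as.character(p$nodes$index))
    m <- subgraph_distance(p, g, asm_mapping(pairs))
    expect_equal(m$total, 0)
    expect_equal(m$struct_d + m$label_d + m$dir_d + m$node_d, 0)
  }
  # skipping one of four nodes costs w_n / 4
  toks <- token_table(1:4, c("t", "x", "y", "z"), pos = "NN")
  p4 <- event_pattern("p4", "X", toks,
                      edge_table(c(1L, 1L, 1L), c(2L, 3L, 4L),
                                 c("a", "b", "c")),
                      tibble::tibble(node = 1L, role = "Trigger",
                                     kind = "trigger", subevent_type = ""))
  g4 <- sentence_graph(toks, edge_table(c(1L, 1L, 1L), c(2L, 3L, 4L),
                                        c("a", "b", "c")))
  w <- distance_weights(w_n = 2)
  m4 <- subgraph_distance(
    p4, g4, asm_mapping(c("1" = 1L, "2" = 2L, "3" = 3L), skipped = 4L), w)
  expect_equal(m4$node_d, 0.25)
  expect_equal(m4$total, 0.25 * 2)
  expect_error(
    subgraph_distance(p4, g4, asm_mapping(c("2" = 2L, "3" = 3L, "4" = 4L),
                                          skipped = 1L)),
    "essential")
})

test_that("subgraph distance equals an independent straight-line recomputation", {
  w <- distance_weights(1, 2, 3, 4)
  for (seed in 1:25) {
    pr <- random_match_pair(seed)
    cand <- asmevents:::node_candidates(pr$p, pr$g, match_policy())
    # build a random admissible full mapping, if any
    set.seed(seed + 1000)
    nodes <- pr$p$nodes$index
    pairs <- integer(0)
    ok <- TRUE
    for (v in nodes) {
      free <- setdiff(cand[[as.character(v)]], pairs)
      if (!length(free)) { ok <- FALSE; break }
      pairs[as.character(v)] <- free[sample.int(length(free), 1)]
    }
    if (!ok) next
    m <- subgraph_distance(pr$p, pr$g, asm_mapping(pairs), w)
    want <- oracle_distance(pr$p, pr$g, as.list(pairs), integer(), w)
    expect_equal(m$total, want)
  }
})

test_that("find_matches honors thresholds on the reference patterns", {
  we <- worked_example()
  doc <- anonymize_entities(we$doc)
  g <- doc$sentences[[1]]
  e1c <- we$expected_patterns$E1c
  expect_length(find_matches(e1c, g, t = 0), 1)
  # E1d (nsubj) against a sentence with only rcmod(ligation, lead)
  toks <- token_table(1:2, c("lead", "ligation"), pos = c("VBP", "NN"))
  g2 <- sentence_graph(toks, edge_table(2L, 1L, "rcmod"))
  e1d <- we$expected_patterns$E1d
  w <- distance_weights()
  hit <- find_matches(e1d, g2, w, t = w$w_l + w$w_d)
  expect_length(hit, 1)
  expect_equal(hit[[1]]$label_d, 1)
  expect_equal(hit[[1]]$dir_d, 1)
  expect_length(find_matches(e1d, g2, w, t = w$w_l + w$w_d - 0.5), 0)
})

test_that("find_matches equals the brute-force oracle on random graph pairs", {
  for (seed in 1:60) {
    pr <- random_match_pair(seed)
    t <- c(0, 1, 2.5)[1 + seed %% 3]
    for (sk in c(FALSE, TRUE)) {
      a <- find_matches(pr$p, pr$g, t = t, allow_skip = sk)
      b <- brute_force_matches(pr$p, pr$g, t = t, allow_skip = sk)
      expect_identical(match_keys(a, pr$p), match_keys(b, pr$p))
    }
  }
})

test_that("distance axioms hold: zero iff exact, monotone thresholds, skip pricing", {
  for (seed in 1:25) {
    pr <- random_match_pair(seed)
    w <- distance_weights()
    m1 <- find_matches(pr$p, pr$g, w, t = 1, allow_skip = TRUE)
    for (m in m1) {
      exact <- m$struct_d == 0 && m$label_d == 0 && m$dir_d == 0 &&
        length(m$mapping$skipped) == 0
      expect_equal(m$total == 0, exact)
    }
    # monotonicity of the match set in t
    m0 <- find_matches(pr$p, pr$g, w, t = 0)
    m2 <- find_matches(pr$p, pr$g, w, t = 2)
    expect_true(all(match_keys(m0, pr$p) %in% match_keys(m2, pr$p)))
    # skipping priced out reproduces the fully injective matcher
    w_hi <- distance_weights(w_n = 3 * nrow(pr$p$nodes))
    a <- find_matches(pr$p, pr$g, w_hi, t = 2, allow_skip = TRUE)
    b <- find_matches(pr$p, pr$g, w_hi, t = 2, allow_skip = FALSE)
    expect_identical(match_keys(a, pr$p), match_keys(b, pr$p))
  }
})

test_that("brute force guard and degenerate inputs behave", {
  toks <- token_table(1:11, paste0("t", 1:11), pos = "NN")
  ed <- edge_table(rep(1L, 10), 2:11, paste0("l", 1:10))
  big <- event_pattern("big", "X", toks, ed,
                       tibble::tibble(node = 1L, role = "Trigger",
                                      kind = "trigger", subevent_type = ""))
  g <- sentence_graph(toks, ed)
  expect_error(brute_force_matches(big, g), "guarded")
  # empty sentence graph
  p1 <- event_pattern("p1", "X", token_table(1L, "t1", pos = "NN"),
                      edge_table(),
                      tibble::tibble(node = 1L, role = "Trigger",
                                     kind = "trigger", subevent_type = ""))
  g0 <- sentence_graph(token_table(1L, "other", pos = "NN"), edge_table())
  expect_length(brute_force_matches(p1, g0, t = 100), 0)
  # 1-node pattern, huge threshold: one match per matching token
  gm <- sentence_graph(token_table(1:3, c("t1", "t1", "x"), pos = "NN"),
                       edge_table())
  expect_length(brute_force_matches(p1, gm, t = 100), 2)
})

test_that("matches serialize to JSON lines", {
  we <- worked_example()
  doc <- anonymize_entities(we$doc)
  ms <- find_matches(we$expected_patterns$E1c, doc$sentences[[1]], t = 0)
  js <- matches_to_json(ms)
  expect_length(js, 1)
  parsed <- jsonlite::fromJSON(js[1])
  expect_equal(parsed$total, 0)
  expect_equal(parsed$image$`20`, 20)
})
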