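test_that("two shortest paths connect the worked-example triggers", {
  we <- worked_example()
  g <- we$doc$sentences[[1]]
  ps <- shortest_paths_undirected(g, 20L, 6L)
  expect_length(ps, 2)
  expect_setequal(vapply(ps, function(p) p$edges$label, ""),
                  c("nsubj", "rcmod"))
  # degenerate endpoints
  same <- shortest_paths_undirected(g, 20L, 20L)
  expect_length(same, 1)
  expect_equal(same[[1]]$nodes, 20L)
  expect_equal(nrow(same[[1]]$edges), 0)
})

test_that("shortest and bounded simple paths agree with brute-force enumeration", {
  enumerate_paths <- function(g, a, b, max_len) {
    adj <- list()
    for (k in seq_len(nrow(g$edges))) {
      gv <- g$edges$governor[k]; dp <- g$edges$dependent[k]
      adj[[as.character(gv)]] <- c(adj[[as.character(gv)]], dp)
      adj[[as.character(dp)]] <- c(adj[[as.character(dp)]], gv)
    }
    out <- list()
    dfs <- function(node, path) {
      if (node == b) { out[[length(out) + 1L]] <<- path; return() }
      if (length(path) > max_len) return()
      for (nx in unique(adj[[as.character(node)]])) {
        if (!nx %in% path) dfs(nx, c(path, nx))
      }
    }
    dfs(a, a)
    out
  }
  for (seed in 1:12) {
    set.seed(seed)
    n <- sample(6:7, 1)
    toks <- token_table(1:n, paste0("t", 1:n), pos = "NN")
    ed <- edge_table()
    for (i in 2:n) {
      ed <- dplyr::bind_rows(ed, edge_table(sample(i - 1, 1), i, "dep"))
    }
    extra <- sample(n, 2)
    if (!any(ed$governor == extra[1] & ed$dependent == extra[2]) &&
        extra[1] != extra[2]) {
      ed <- dplyr::bind_rows(ed, edge_table(extra[1], extra[2], "dep2"))
    }
    g <- sentence_graph(toks, ed, "s")
    ab <- sample(n, 2)
    want_nodes <- enumerate_paths(g, ab[1], ab[2], max_len = n)
    lens <- lengths(want_nodes)
    # shortest: brute-force keeps only minimal length node sequences,
    # expanded over parallel edge choices
    got <- shortest_paths_undirected(g, ab[1], ab[2])
    got_nodes <- unique(lapply(got, `[[`, "nodes"))
    expect_setequal(
      vapply(got_nodes, paste, "", collapse = ","),
      vapply(want_nodes[lens == min(lens)], paste, "", collapse = ","))
    # all simple paths up to a cap
    cap <- min(lens) + 1L
    got_all <- all_acyclic_paths(g, ab[1], ab[2], max_len = cap - 1L)
    expect_setequal(
      vapply(unique(lapply(got_all, `[[`, "nodes")), paste, "",
             collapse = ","),
      vapply(want_nodes[lens <= cap], paste, "", collapse = ","))
  }
})

test_that("a triangle with a chord yields two bounded acyclic paths", {
  toks <- token_table(1:3, c("a", "c", "b"), pos = "NN")
  ed <- edge_table(c(1L, 2L, 1L), c(2L, 3L, 3L), c("x", "y", "z"))
  g <- sentence_graph(toks, ed)
  expect_length(all_acyclic_paths(g, 1L, 3L, max_len = 3), 2)
  # a tree gives exactly the one tree path
  tree <- sentence_graph(toks, edge_table(c(1L, 2L), c(2L, 3L), c("x", "y")))
  expect_length(all_acyclic_paths(tree, 1L, 3L, max_len = 5), 1)
})

test_that("worked-example induction yields the five reference patterns", {
  we <- worked_example()
  doc <- anonymize_entities(we$doc)
  pats <- induce_patterns(doc)
  pos <- purrr::keep(pats, function(p) p$event_type == "Positive_regulation")
  expect_length(pos, 5)
  for (exp_p in we$expected_patterns) {
    hits <- vapply(pos, patterns_isomorphic, logical(1), q = exp_p)
    expect_equal(sum(hits), 1,
                 info = paste("expected pattern", exp_p$pattern_id))
  }
  # unions subsume the individual paths (edge-set identity)
  edge_key <- function(p) {
    sort(paste(p$edges$label, p$edges$governor, p$edges$dependent))
  }
  ek <- lapply(we$expected_patterns, edge_key)
  expect_setequal(ek$E1a, union(ek$E1c, ek$E1d))
  expect_setequal(ek$E1b, union(ek$E1c, ek$E1e))
})

test_that("single-argument events induce exactly one pattern", {
  corp <- generate_event_corpus(corpus_spec(n_docs = 1,
                                            depth_probs = c(1, 0, 0),
                                            two_arg_prob = 0, seed = 3))
  pats <- induce_patterns(corp$train[[1]])
  expect_length(pats, 1)
  expect_false(is_higher_order(pats[[1]]))
})

test_that("union pattern edges equal the union of individual pattern edges", {
  corp <- generate_event_corpus(corpus_spec(n_docs = 4,
                                            depth_probs = c(1, 0, 0),
                                            two_arg_prob = 1, seed = 8))
  for (doc in corp$train) {
    pats <- induce_patterns(doc)
    expect_length(pats, 3)  # two individual paths + one union
    nargs <- vapply(pats, function(p) {
      sum(p$bindings$kind != "trigger")
    }, integer(1))
    uni <- pats[[which(nargs == 2)]]
    indiv <- pats[nargs == 1]
    edge_key <- function(p) {
      sort(paste(p$edges$label, p$edges$governor, p$edges$dependent))
    }
    expect_setequal(edge_key(uni),
                    union(edge_key(indiv[[1]]), edge_key(indiv[[2]])))
  }
})

test_that("all-paths induction is a superset of shortest-path induction", {
  corp <- generate_event_corpus(corpus_spec(n_docs = 4, seed = 77))
  for (doc in corp$train) {
    sp <- induce_patterns(doc, mode = "shortest")
    ap <- induce_patterns(doc, mode = "all_paths")
    expect_gte(length(ap), length(sp))
    for (p in sp) {
      expect_true(any(vapply(ap, patterns_isomorphic, logical(1), q = p)))
    }
  }
})

test_that("induced patterns are connected and contain their essential nodes", {
  corp <- generate_event_corpus(corpus_spec(n_docs = 5,
                                            depth_probs = c(0.4, 0.4, 0.2),
                                            seed = 15))
  pats <- unlist(lapply(corp$train, induce_patterns), recursive = FALSE)
  for (p in pats) {
    expect_true(all(p$essential %in% p$nodes$index))
    expect_true(asmevents:::pattern_connected(p))
  }
})

test_that("deduplication keeps one copy per isomorphism class", {
  we <- worked_example()
  doc <- anonymize_entities(we$doc)
  pats <- induce_patterns(doc)
  doubled <- c(pats, pats)
  expect_length(dedup_patterns(doubled), length(pats))
  # E1a and E1b differ in one edge and are both retained
  expect_length(dedup_patterns(we$expected_patterns[c("E1a", "E1b")]), 2)
  # 50 random patterns with 10 planted duplicates -> 40 retained
  set.seed(5)
  base <- lapply(1:40, function(i) {
    toks <- token_table(1:2, c(paste0("trig", i), paste0("arg", i)),
                        pos = "NN")
    event_pattern(paste0("b", i), "X", toks,
                  edge_table(1L, 2L, paste0("lab", i %% 7)),
                  tibble::tibble(node = 1:2, role = c("Trigger", "Theme"),
                                 kind = c("trigger", "trigger"),
                                 subevent_type = ""))
  })
  dupes <- lapply(sample(base, 10), function(p) {
    p$pattern_id <- paste0(p$pattern_id, "_dup")
    # shift token positions: isomorphism ignores provenance indices
    p$nodes$index <- p$nodes$index + 10L
    p$edges$governor <- p$edges$governor + 10L
    p$edges$dependent <- p$edges$dependent + 10L
    p$bindings$node <- p$bindings$node + 10L
    p$essential <- p$essential + 10L
    p
  })
  expect_length(dedup_patterns(c(base, dupes)), 40)
})

test_that("the pattern store round-trips losslessly", {
  corp <- generate_event_corpus(corpus_spec(n_docs = 3,
                                            depth_probs = c(0.3, 0.5, 0.2),
                                            seed = 23))
  pats <- induce_all(corp$train)
  pats[[1]]$threshold <- 2.5
  lines <- write_pattern_store(pats)
  back <- read_pattern_store(lines)
  expect_length(back, length(pats))
  for (i in seq_along(pats)) {
    expect_equal(back[[i]]$pattern_id, pats[[i]]$pattern_id)
    expect_equal(back[[i]]$event_type, pats[[i]]$event_type)
    expect_equal(back[[i]]$threshold, pats[[i]]$threshold)
    expect_equal(back[[i]]$nodes$lemma, pats[[i]]$nodes$lemma)
    expect_equal(back[[i]]$edges, pats[[i]]$edges)
    expect_equal(back[[i]]$bindings, pats[[i]]$bindings)
    expect_true(patterns_isomorphic(back[[i]], pats[[i]]))
  }
})

test_that("induction requires an anonymized document", {
  we <- worked_example()
  expect_error(induce_patterns(we$doc), "anonymized")
})
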