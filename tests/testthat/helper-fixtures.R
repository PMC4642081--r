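# Shared fixture builders; everything is generated in code, seeded.

# random labeled sentence graph / pattern pair for matcher oracle checks
random_match_pair <- function(seed, max_pattern_nodes = 5L) {
  set.seed(seed)
  vocab <- paste0("w", 1:6)
  labs <- paste0("l", 1:4)
  ns <- sample(5:8, 1)
  toks <- token_table(1:ns, sample(vocab, ns, replace = TRUE),
                      pos = sample(c("NN", "VB"), ns, replace = TRUE))
  ed <- edge_table()
  for (i in 2:ns) {
    ed <- dplyr::bind_rows(ed, edge_table(sample(i - 1, 1), i,
                                          sample(labs, 1)))
  }
  for (k in seq_len(sample(0:2, 1))) {
    a <- sample(ns, 2); l <- sample(labs, 1)
    if (!any(ed$governor == a[1] & ed$dependent == a[2] & ed$label == l)) {
      ed <- dplyr::bind_rows(ed, edge_table(a[1], a[2], l))
    }
  }
  g <- sentence_graph(toks, ed, "s1")
  np <- sample(2:max_pattern_nodes, 1)
  ptoks <- token_table(1:np, sample(vocab, np, replace = TRUE),
                       pos = sample(c("NN", "VB"), np, replace = TRUE))
  ped <- edge_table()
  for (i in 2:np) {
    ped <- dplyr::bind_rows(ped, edge_table(sample(i - 1, 1), i,
                                            sample(labs, 1)))
  }
  ess <- sort(sample(np, sample(1:min(2, np), 1)))
  b <- tibble::tibble(node = ess, role = "Trigger", kind = "trigger",
                      subevent_type = "")
  list(p = event_pattern("rp", "X", ptoks, ped, b), g = g)
}

match_keys <- function(matches, p) {
  sort(vapply(matches, function(m) {
    paste(asmevents:::match_full_key(m, p), round(m$total, 6),
          m$struct_d, m$label_d, m$dir_d, round(m$node_d, 6))
  }, character(1)))
}

pattern_ids <- function(patterns) vapply(patterns, `[[`, "", "pattern_id")

induce_all <- function(docs, ...) {
  dedup_patterns(unlist(lapply(docs, induce_patterns, ...),
                        recursive = FALSE))
}

final_sigs <- function(cands) {
  sort(vapply(finalize_events(cands), `[[`, "", "sig"))
}

# independent straight-line recomputation of the subgraph distance for a
# given full mapping, coded directly against an igraph view of the sentence
oracle_distance <- function(p, g, pairs, skipped, w) {
  ig <- igraph::simplify(asmevents:::as_igraph_undirected(g))
  comp <- c(s = 0, l = 0, d = 0)
  for (k in seq_len(nrow(p$edges))) {
    gv <- p$edges$governor[k]; dp <- p$edges$dependent[k]
    if (gv %in% skipped || dp %in% skipped) next
    u <- pairs[[as.character(gv)]]; v <- pairs[[as.character(dp)]]
    sp <- suppressWarnings(igraph::all_shortest_paths(
      ig, from = as.character(u), to = as.character(v)))
    node_paths <- lapply(sp$vpaths, function(x) {
      as.integer(igraph::V(ig)$name[x])
    })
    if (!length(node_paths)) return(Inf)
    best <- NULL
    for (np in node_paths) {
      len <- length(np) - 1L
      if (len == 1L) {
        sel <- (g$edges$governor == u & g$edges$dependent == v) |
          (g$edges$governor == v & g$edges$dependent == u)
        opts <- cbind(as.integer(g$edges$label[sel] != p$edges$label[k]),
                      as.integer(g$edges$governor[sel] != u))
        j <- which.min(opts[, 1] + opts[, 2])
        cand <- c(0L, opts[j, 1], opts[j, 2])
      } else {
        lab_present <- FALSE; consistent <- FALSE
        for (i in seq_len(len)) {
          x <- np[i]; y <- np[i + 1L]
          sel <- ((g$edges$governor == x & g$edges$dependent == y) |
                    (g$edges$governor == y & g$edges$dependent == x)) &
            g$edges$label == p$edges$label[k]
          if (any(sel)) {
            lab_present <- TRUE
            if (any(g$edges$governor[sel] == x)) consistent <- TRUE
          }
        }
        cand <- c(len - 1L, as.integer(!lab_present), as.integer(!consistent))
      }
      if (is.null(best) || (cand[2] + cand[3]) < (best[2] + best[3])) {
        best <- cand
      }
    }
    comp <- comp + c(s = best[1], l = best[2], d = best[3])
  }
  w$w_s * comp[["s"]] + w$w_l * comp[["l"]] + w$w_d * comp[["d"]] +
    w$w_n * length(skipped) / nrow(p$nodes)
}
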