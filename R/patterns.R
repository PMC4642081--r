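#' Construct an event pattern
#'
#' An event pattern is a connected dependency subgraph G_r induced from an
#' annotated training event, together with the event type, role bindings
#' (which nodes correspond to the trigger and to each argument), the set of
#' essential nodes V_r' (trigger, sub-event trigger and argument nodes, never
#' skippable during matching) and a per-pattern distance threshold.
#'
#' @param pattern_id identifier string.
#' @param event_type event type string (e.g. `"Positive_regulation"`).
#' @param nodes token tibble (subset of a sentence's [token_table()]).
#' @param edges [edge_table()] over `nodes$index`.
#' @param bindings tibble with columns `node` (token index), `role`
#'   (`"Trigger"`, `"Theme"`, `"Cause"`, ...), `kind` (`"trigger"`,
#'   `"entity"` or `"event"`) and `subevent_type` (`""` unless
#'   `kind == "event"`).
#' @param threshold per-pattern distance threshold (`NA` until learned).
#' @param provenance list with `doc`, `sentence`, `event` identifiers.
#' @return object of class `event_pattern`.
#' @export
event_pattern <- function(pattern_id, event_type, nodes, edges, bindings,
                          threshold = NA_real_, provenance = list()) {
  nodes <- nodes[order(nodes$index), ]
  if (!all(bindings$node %in% nodes$index)) {
    abort("binding references a node outside the pattern")
  }
  bad <- setdiff(c(edges$governor, edges$dependent), nodes$index)
  if (length(bad)) abort("pattern edge references a node outside the pattern")
  p <- structure(
    list(pattern_id = pattern_id, event_type = event_type, nodes = nodes,
         edges = edges, bindings = bindings,
         essential = sort(unique(bindings$node)),
         threshold = threshold, provenance = provenance),
    class = "event_pattern"
  )
  if (!pattern_connected(p)) abort("pattern graph is not connected")
  p
}

pattern_connected <- function(p) {
  n <- nrow(p$nodes)
  if (n <= 1) return(TRUE)
  reach <- p$nodes$index[1]
  repeat {
    nxt <- unique(c(
      reach,
      p$edges$dependent[p$edges$governor %in% reach],
      p$edges$governor[p$edges$dependent %in% reach]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  length(reach) == n
}

#' @export
print.event_pattern <- function(x, ...) {
  b <- x$bindings
  cat("<event_pattern ", x$pattern_id, " [", x$event_type, "] t=",
      x$threshold, ">\n", sep = "")
  cat(" bindings: ",
      paste(sprintf("%s:%s%s", b$role, node_ref(x, b$node),
                    ifelse(nzchar(b$subevent_type),
                           paste0("(", b$subevent_type, ")"), "")),
            collapse = " "), "\n", sep = "")
  cat(" edges: ", paste(pattern_edge_strings(x), collapse = " "), "\n", sep = "")
  invisible(x)
}

node_ref <- function(p, idx) {
  k <- match(idx, p$nodes$index)
  paste0(p$nodes$surface[k], "-", idx, "/", p$nodes$pos[k])
}

pattern_edge_strings <- function(p) {
  if (!nrow(p$edges)) return(character())
  sprintf("%s(%s, %s)", p$edges$label, node_ref(p, p$edges$governor),
          node_ref(p, p$edges$dependent))
}

#' Is a pattern higher-order?
#'
#' A higher-order pattern encodes a nested event: at least one argument is
#' bound to a sub-event trigger. Lower-order patterns take only entities as
#' arguments.
#'
#' @param p an [event_pattern()].
#' @return logical.
#' @export
is_higher_order <- function(p) any(p$bindings$kind == "event")

#' All undirected shortest paths between two tokens
#'
#' Edge directionality is ignored; when multiple paths of the same (shortest)
#' length exist, all of them are returned. Parallel dependency edges between
#' the same token pair count as distinct paths.
#'
#' @param g a [sentence_graph()].
#' @param a,b token indices.
#' @return list of paths; each path is a list with `nodes` (token index
#'   sequence from `a` to `b`) and `edges` (the traversed edge rows).
#'   Empty list if `a` and `b` are disconnected.
#' @export
shortest_paths_undirected <- function(g, a, b) {
  stopifnot(a %in% g$tokens$index, b %in% g$tokens$index)
  if (a == b) {
    return(list(list(nodes = a, edges = g$edges[0, ])))
  }
  ig <- igraph::simplify(as_igraph_undirected(g), remove.multiple = TRUE)
  sp <- suppressWarnings(
    igraph::all_shortest_paths(ig, from = as.character(a), to = as.character(b)))
  node_paths <- unique(lapply(sp$vpaths, function(v) {
    as.integer(igraph::V(ig)$name[v])
  }))
  node_paths <- node_paths[lengths(node_paths) > 0]
  expand_parallel_edges(g, node_paths)
}

#' All acyclic (simple) paths between two tokens up to a length cap
#'
#' @param g a [sentence_graph()].
#' @param a,b token indices.
#' @param max_len maximum number of edges per path (>= 1).
#' @return list of paths as in [shortest_paths_undirected()]; a superset of
#'   the shortest paths whenever `max_len` is large enough.
#' @export
all_acyclic_paths <- function(g, a, b, max_len) {
  stopifnot(max_len >= 1, a %in% g$tokens$index, b %in% g$tokens$index)
  if (a == b) return(list(list(nodes = a, edges = g$edges[0, ])))
  ig <- igraph::simplify(as_igraph_undirected(g), remove.multiple = TRUE)
  sp <- igraph::all_simple_paths(ig, from = as.character(a),
                                 to = as.character(b), cutoff = max_len)
  node_paths <- unique(lapply(sp, function(v) as.integer(igraph::V(ig)$name[v])))
  expand_parallel_edges(g, node_paths)
}

# turn node sequences into edge paths, enumerating every choice of parallel
# edge on each hop (so nsubj(x,y) and rcmod(y,x) yield two distinct paths).
expand_parallel_edges <- function(g, node_paths) {
  out <- list()
  for (np in node_paths) {
    hop_edges <- lapply(seq_len(length(np) - 1L), function(i) {
      x <- np[i]; y <- np[i + 1L]
      which((g$edges$governor == x & g$edges$dependent == y) |
              (g$edges$governor == y & g$edges$dependent == x))
    })
    combos <- expand.grid(rev(hop_edges), KEEP.OUT.ATTRS = FALSE)
    combos <- combos[, rev(seq_along(hop_edges)), drop = FALSE]
    for (r in seq_len(nrow(combos))) {
      out[[length(out) + 1L]] <-
        list(nodes = np, edges = g$edges[as.integer(combos[r, ]), ])
    }
  }
  # deterministic order: by path length, then node sequence, then edge rows
  keys <- vapply(out, function(p) {
    paste(length(p$nodes),
          paste(sprintf("%04d", p$nodes), collapse = ","),
          paste(p$edges$label, p$edges$governor, p$edges$dependent,
                collapse = ";"))
  }, character(1))
  out[order(keys)]
}

normalize_role <- function(role) sub("[0-9]+$", "", role)

#' Induce event patterns from an annotated document
#'
#' For every annotated event, the shortest undirected dependency paths from
#' the trigger to each argument are collected (all paths of the minimal
#' length). Each (argument, path) pair yields one individual pattern; events
#' with two or more arguments sharing the trigger additionally yield union
#' patterns, one per combination of per-argument path choices (capped at
#' `max_unions`). Multi-token triggers contribute the union of pairwise
#' trigger-token shortest paths to every pattern. Sub-event arguments are
#' represented by their trigger token, bound as a sub-event node; entity
#' arguments by their (anonymized) head token. In `all_paths` mode every
#' acyclic path up to `shortest length + extra_len` is considered instead of
#' only the shortest ones.
#'
#' @param doc an anonymized [standoff_document()] (see
#'   [anonymize_entities()]).
#' @param mode `"shortest"` or `"all_paths"`.
#' @param extra_len in `all_paths` mode, how many edges beyond the shortest
#'   length to allow (default 2).
#' @param max_unions cap on union patterns per event (default 8).
#' @return list of [event_pattern()] objects.
#' @export
induce_patterns <- function(doc, mode = c("shortest", "all_paths"),
                            extra_len = 2L, max_unions = 8L) {
  mode <- match.arg(mode)
  if (is.null(doc$anonymized) || !isTRUE(doc$anonymized)) {
    abort("document must be anonymized before pattern induction")
  }
  patterns <- list()
  for (ev in doc$events) {
    pats <- induce_event_patterns(doc, ev, mode, extra_len, max_unions)
    patterns <- c(patterns, pats)
  }
  for (i in seq_along(patterns)) {
    patterns[[i]]$pattern_id <- sprintf("%s_p%03d", doc$doc_id, i)
  }
  patterns
}

induce_event_patterns <- function(doc, ev, mode, extra_len, max_unions) {
  g <- doc$sentences[[ev$sentence]]
  absorbed <- g$tokens$index[g$tokens$absorbed]
  trig <- setdiff(ev$trigger_tokens, absorbed)
  if (!length(trig)) return(list())

  # trigger core: union of all pairwise shortest paths among trigger tokens
  core_edges <- g$edges[0, ]; core_nodes <- trig
  if (length(trig) > 1) {
    for (i in seq_len(length(trig) - 1L)) {
      for (j in seq((i + 1L), length(trig))) {
        ps <- shortest_paths_undirected(g, trig[i], trig[j])
        if (!length(ps)) {
          warn(paste0("trigger tokens of ", ev$id, " are disconnected; skipped"))
          return(list())
        }
        for (p in ps) {
          core_nodes <- union(core_nodes, p$nodes)
          core_edges <- unique(bind_rows(core_edges, p$edges))
        }
      }
    }
  }

  # argument anchors
  arg_info <- list()
  for (k in seq_len(nrow(ev$args))) {
    role <- normalize_role(ev$args$role[k]); tg <- ev$args$target[k]
    if (startsWith(tg, "T")) {
      node <- doc$entities$head_token[doc$entities$id == tg]
      kind <- "entity"; sub_ty <- ""
    } else {
      sub <- doc$events[[tg]]
      node <- setdiff(sub$trigger_tokens, absorbed)[1]
      kind <- "event"; sub_ty <- sub$type
    }
    if (is.na(node) || !length(node)) next
    arg_info[[length(arg_info) + 1L]] <-
      list(role = role, node = node, kind = kind, subevent_type = sub_ty)
  }
  if (!length(arg_info)) return(list())

  # per-argument path alternatives (from the nearest trigger token)
  arg_paths <- list()
  for (a in arg_info) {
    best <- list(); best_len <- Inf
    for (tt in trig) {
      ps <- shortest_paths_undirected(g, tt, a$node)
      if (!length(ps)) next
      len <- length(ps[[1]]$nodes)
      if (len < best_len) { best <- ps; best_len <- len }
      else if (len == best_len) best <- c(best, ps)
    }
    if (!length(best)) {
      warn(paste0("argument ", a$role, " of ", ev$id,
                  " disconnected from trigger; pattern skipped"))
      next
    }
    if (mode == "all_paths") {
      allp <- list()
      for (tt in trig) {
        ps <- all_acyclic_paths(g, tt, a$node,
                                max_len = (best_len - 1L) + extra_len)
        allp <- c(allp, ps)
      }
      best <- unique_paths(allp)
    }
    arg_paths[[length(arg_paths) + 1L]] <- list(arg = a, paths = best)
  }
  if (!length(arg_paths)) return(list())

  build <- function(chosen) {
    # chosen: list of (arg, path)
    nodes <- core_nodes; edges <- core_edges
    bindings <- tibble(node = trig, role = "Trigger", kind = "trigger",
                       subevent_type = "")
    for (cp in chosen) {
      nodes <- union(nodes, cp$path$nodes)
      edges <- unique(bind_rows(edges, cp$path$edges))
      bindings <- bind_rows(bindings, tibble(
        node = cp$arg$node, role = cp$arg$role, kind = cp$arg$kind,
        subevent_type = cp$arg$subevent_type))
    }
    ntab <- g$tokens[match(sort(nodes), g$tokens$index), ]
    event_pattern("tmp", ev$type, ntab, edges, bindings,
                  provenance = list(doc = doc$doc_id, sentence = ev$sentence,
                                    event = ev$id))
  }

  pats <- list()
  # individual patterns: one per (argument, path)
  for (ap in arg_paths) {
    for (p in ap$paths) {
      pats[[length(pats) + 1L]] <- build(list(list(arg = ap$arg, path = p)))
    }
  }
  # union patterns over the cross-product of per-argument path choices
  if (length(arg_paths) >= 2) {
    counts <- vapply(arg_paths, function(ap) length(ap$paths), integer(1))
    combos <- expand.grid(rev(lapply(counts, seq_len)), KEEP.OUT.ATTRS = FALSE)
    combos <- combos[, rev(seq_along(counts)), drop = FALSE]
    combos <- combos[order(apply(combos, 1, paste, collapse = ",")), ,
                     drop = FALSE]
    n_take <- min(nrow(combos), max_unions)
    for (r in seq_len(n_take)) {
      chosen <- lapply(seq_along(arg_paths), function(i) {
        list(arg = arg_paths[[i]]$arg,
             path = arg_paths[[i]]$paths[[combos[r, i]]])
      })
      pats[[length(pats) + 1L]] <- build(chosen)
    }
  }
  pats
}

unique_paths <- function(paths) {
  keys <- vapply(paths, function(p) {
    paste(paste(p$nodes, collapse = ","),
          paste(p$edges$label, p$edges$governor, p$edges$dependent,
                collapse = ";"))
  }, character(1))
  paths[!duplicated(keys)][order(unique(keys))]
}

node_content_key <- function(nodes) {
  paste(nodes$lemma, nodes$relaxed_pos, nodes$is_entity, nodes$entity_type,
        sep = "\r")
}

#' Test two patterns for exact isomorphism
#'
#' Patterns are isomorphic when a node bijection preserves matchable node
#' content (lemma and relaxed POS, plus entity type), every labeled directed
#' edge, and every role binding. Pattern ids, token positions and sub-event
#' provenance types are ignored.
#'
#' @param p,q [event_pattern()] objects.
#' @return logical.
#' @export
patterns_isomorphic <- function(p, q) {
  if (p$event_type != q$event_type) return(FALSE)
  if (nrow(p$nodes) != nrow(q$nodes) || nrow(p$edges) != nrow(q$edges)) {
    return(FALSE)
  }
  pk <- node_content_key(p$nodes); qk <- node_content_key(q$nodes)
  if (!identical(sort(pk), sort(qk))) return(FALSE)
  role_key <- function(pat, idx) {
    b <- pat$bindings[pat$bindings$node == idx, ]
    paste(sort(paste(b$role, b$kind)), collapse = "|")
  }
  p_roles <- vapply(p$nodes$index, function(i) role_key(p, i), character(1))
  q_roles <- vapply(q$nodes$index, function(i) role_key(q, i), character(1))
  edge_set <- function(pat, perm) {
    # perm maps pat node position -> target node index
    gv <- perm[match(pat$edges$governor, pat$nodes$index)]
    dp <- perm[match(pat$edges$dependent, pat$nodes$index)]
    sort(paste(pat$edges$label, gv, dp))
  }
  q_edges_ref <- sort(paste(q$edges$label, q$edges$governor, q$edges$dependent))
  n <- nrow(p$nodes)
  cand <- lapply(seq_len(n), function(i) {
    q$nodes$index[qk == pk[i] & q_roles == p_roles[i]]
  })
  if (any(lengths(cand) == 0)) return(FALSE)
  assign <- integer(n)
  found <- FALSE
  bt <- function(i) {
    if (found) return()
    if (i > n) {
      if (identical(edge_set(p, assign), q_edges_ref)) found <<- TRUE
      return()
    }
    for (c in cand[[i]]) {
      if (c %in% assign[seq_len(i - 1L)]) next
      assign[i] <<- c
      bt(i + 1L)
      if (found) return()
    }
    assign[i] <<- 0L
  }
  bt(1L)
  found
}

#' Remove exactly isomorphic duplicate patterns
#'
#' Keeps the earliest pattern (input order) of each isomorphism class; two
#' patterns of the same event type are duplicates when some bijection
#' preserves node content, edge labels, edge directions and role bindings
#' (exact subgraph-matching deduplication).
#'
#' @param patterns list of [event_pattern()].
#' @return the deduplicated list, in original order.
#' @export
dedup_patterns <- function(patterns) {
  if (length(patterns) <= 1) return(patterns)
  # cheap invariant key prunes the quadratic comparison
  keys <- vapply(patterns, function(p) {
    paste(p$event_type, nrow(p$nodes), nrow(p$edges),
          paste(sort(node_content_key(p$nodes)), collapse = ";"),
          paste(sort(p$edges$label), collapse = ";"),
          paste(sort(paste(p$bindings$role, p$bindings$kind)), collapse = ";"))
  }, character(1))
  keep <- logical(length(patterns))
  for (i in seq_along(patterns)) {
    dup <- FALSE
    for (j in which(keep)) {
      if (keys[i] == keys[j] && patterns_isomorphic(patterns[[i]],
                                                    patterns[[j]])) {
        dup <- TRUE; break
      }
    }
    keep[i] <- !dup
  }
  patterns[keep]
}

#' Serialize patterns to a line-oriented store
#'
#' One pattern per line with tab-separated fields: id, event type, threshold,
#' `|`-separated node declarations `surface-i/POS/lemma/entity_type`,
#' `|`-separated edges in `label(surface-i/POS, surface-j/POS)` notation,
#' `|`-separated bindings `role:kind:node:subevent_type`, and provenance.
#' The store round-trips losslessly through [read_pattern_store()].
#'
#' @param patterns list of [event_pattern()].
#' @param path optional file path to write to.
#' @return character vector of lines, invisibly when `path` is given.
#' @export
write_pattern_store <- function(patterns, path = NULL) {
  lines <- vapply(patterns, function(p) {
    nodes <- paste(sprintf("%s-%d/%s/%s/%s", p$nodes$surface, p$nodes$index,
                           p$nodes$pos, p$nodes$lemma, p$nodes$entity_type),
                   collapse = "|")
    edges <- paste(pattern_edge_strings(p), collapse = "|")
    binds <- paste(sprintf("%s:%s:%d:%s", p$bindings$role, p$bindings$kind,
                           p$bindings$node, p$bindings$subevent_type),
                   collapse = "|")
    prov <- paste(p$provenance$doc %||% "", p$provenance$sentence %||% "",
                  p$provenance$event %||% "", sep = "|")
    paste(p$pattern_id, p$event_type, p$threshold, nodes, edges, binds, prov,
          sep = "\t")
  }, character(1))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Read patterns back from a line-oriented store
#'
#' @param lines character vector of store lines, or a file path.
#' @return list of [event_pattern()].
#' @export
read_pattern_store <- function(lines) {
  lines <- read_lines_arg(lines, "patterns")
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t")[[1]]
    nd <- strsplit(f[4], "|", fixed = TRUE)[[1]]
    m <- regmatches(nd, regexec("^(.*)-([0-9]+)/([^/]*)/([^/]*)/([^/]*)$", nd))
    nodes <- token_table(
      index = vapply(m, function(x) as.integer(x[3]), integer(1)),
      surface = vapply(m, `[`, "", 2),
      lemma = vapply(m, `[`, "", 5),
      pos = vapply(m, `[`, "", 4),
      entity_type = vapply(m, `[`, "", 6))
    edges <- edge_table()
    if (nzchar(f[5])) {
      es <- strsplit(f[5], "|", fixed = TRUE)[[1]]
      em <- regmatches(es, regexec(
        "^([^(]+)\\(.*-([0-9]+)/[^,]*,[[:space:]]*.*-([0-9]+)/[^)]*\\)$", es))
      edges <- edge_table(
        governor = vapply(em, function(x) as.integer(x[3]), integer(1)),
        dependent = vapply(em, function(x) as.integer(x[4]), integer(1)),
        label = vapply(em, `[`, "", 2))
    }
    bs <- strsplit(f[6], "|", fixed = TRUE)[[1]]
    bm <- strsplit(bs, ":", fixed = TRUE)
    bindings <- tibble(
      node = vapply(bm, function(x) as.integer(x[3]), integer(1)),
      role = vapply(bm, `[`, "", 1),
      kind = vapply(bm, `[`, "", 2),
      subevent_type = vapply(bm, function(x) if (length(x) >= 4) x[4] else "",
                             character(1)))
    pv <- strsplit(f[7], "|", fixed = TRUE)[[1]]
    event_pattern(f[1], f[2], nodes, edges, bindings,
                  threshold = suppressWarnings(as.numeric(f[3])),
                  provenance = list(doc = pv[1] %||% "", sentence = pv[2] %||% "",
                                    event = pv[3] %||% ""))
  })
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
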