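#' Distance weights for the subgraph distance
#'
#' The subgraph distance is
#' `w_s * structDist + w_l * labelDist + w_d * directionalityDist +
#'  w_n * nodeDist`. All weights are non-negative; the default keeps the
#' equal-weights constraint `w_s = w_l = w_d = w_n`.
#'
#' @param w_s,w_l,w_d,w_n non-negative component weights.
#' @return object of class `distance_weights`.
#' @export
distance_weights <- function(w_s = 1, w_l = 1, w_d = 1, w_n = 1) {
  w <- list(w_s = w_s, w_l = w_l, w_d = w_d, w_n = w_n)
  if (any(unlist(w) < 0)) abort("distance weights must be non-negative")
  structure(w, class = "distance_weights")
}

#' Node matching policy
#'
#' Controls when a pattern token may map onto a sentence token:
#' \describe{
#'   \item{EXACT}{identical surface form and POS tag.}
#'   \item{L}{identical lemma.}
#'   \item{P}{identical relaxed POS tag.}
#'   \item{PSL}{the `P*+L` criterion: identical relaxed POS tag and lemma.}
#'   \item{PSL_DSM}{`P*+L`, or the sentence lemma appears among the top-M
#'     distributionally most similar words of the pattern lemma.}
#' }
#' Entity-bound pattern nodes only ever match sentence entity tokens of the
#' same generic type, regardless of criteria.
#'
#' @param criteria one of `"PSL"`, `"EXACT"`, `"L"`, `"P"`, `"PSL_DSM"`.
#' @param dsm_model a [dsm_model()] (required for `PSL_DSM`).
#' @param dsm_top_m positive integer M for the similarity list.
#' @return object of class `match_policy`.
#' @export
match_policy <- function(criteria = c("PSL", "EXACT", "L", "P", "PSL_DSM"),
                         dsm_model = NULL, dsm_top_m = 3L) {
  criteria <- match.arg(criteria)
  if (criteria == "PSL_DSM" && is.null(dsm_model)) {
    abort("PSL_DSM matching requires a dsm_model")
  }
  structure(list(criteria = criteria, dsm_model = dsm_model,
                 dsm_top_m = as.integer(dsm_top_m)),
            class = "match_policy")
}

#' Can a pattern token match a sentence token?
#'
#' @param p_tok,s_tok single-row token tibbles (see [token_table()]).
#' @param policy a [match_policy()].
#' @return logical.
#' @export
node_match <- function(p_tok, s_tok, policy = match_policy()) {
  if (p_tok$is_entity) {
    return(s_tok$is_entity && identical(p_tok$entity_type, s_tok$entity_type))
  }
  if (s_tok$is_entity) return(FALSE)
  base <- switch(policy$criteria,
    EXACT = identical(p_tok$surface, s_tok$surface) &&
      identical(p_tok$pos, s_tok$pos),
    L = identical(p_tok$lemma, s_tok$lemma),
    P = identical(p_tok$relaxed_pos, s_tok$relaxed_pos),
    PSL = ,
    PSL_DSM = identical(p_tok$relaxed_pos, s_tok$relaxed_pos) &&
      identical(p_tok$lemma, s_tok$lemma)
  )
  if (base || policy$criteria != "PSL_DSM") return(base)
  if (!identical(p_tok$relaxed_pos, s_tok$relaxed_pos)) return(FALSE)
  sims <- dsm_similar_lemmas(policy$dsm_model, p_tok$lemma, p_tok$pos,
                             policy$dsm_top_m)
  s_tok$lemma %in% sims
}

# ---- sentence matching context -------------------------------------------

# Precomputes the undirected adjacency list of a sentence and memoizes
# pairwise alignment costs; reused across all edges/mappings of a search.
match_context <- function(g) {
  ctx <- new.env(parent = emptyenv())
  ctx$g <- g
  ctx$adj <- adjacency_list(g)
  ctx$path_memo <- new.env(parent = emptyenv())
  ctx$cost_memo <- new.env(parent = emptyenv())
  ctx
}

# all shortest undirected node-paths between u and v; NULL if disconnected.
ctx_shortest_node_paths <- function(ctx, u, v) {
  key <- paste0(u, "|", v)
  hit <- ctx$path_memo[[key]]
  if (!is.null(hit)) return(if (identical(hit, FALSE)) NULL else hit)
  # BFS from u recording parent sets
  dist <- new.env(parent = emptyenv())
  parents <- new.env(parent = emptyenv())
  assign(as.character(u), 0L, envir = dist)
  frontier <- u
  d <- 0L
  found <- (u == v)
  while (length(frontier) && !found) {
    nxt <- integer()
    for (x in frontier) {
      a <- ctx$adj[[as.character(x)]]
      for (y in unique(a$other)) {
        yk <- as.character(y)
        dy <- dist[[yk]]
        if (is.null(dy)) {
          assign(yk, d + 1L, envir = dist)
          assign(yk, x, envir = parents)
          nxt <- c(nxt, y)
        } else if (dy == d + 1L) {
          assign(yk, c(parents[[yk]], x), envir = parents)
        }
      }
    }
    frontier <- sort(unique(nxt))
    d <- d + 1L
    if (!is.null(dist[[as.character(v)]])) found <- TRUE
  }
  if (u != v && is.null(dist[[as.character(v)]])) {
    ctx$path_memo[[key]] <- FALSE
    return(NULL)
  }
  paths <- list()
  walk <- function(node, acc) {
    if (node == u) {
      paths[[length(paths) + 1L]] <<- c(u, rev(acc))
      return()
    }
    for (p in parents[[as.character(node)]]) walk(p, c(acc, node))
  }
  if (u == v) paths <- list(u) else walk(v, integer())
  # deterministic: lexicographic node order
  paths <- paths[order(vapply(paths, function(p)
    paste(sprintf("%05d", p), collapse = ","), character(1)))]
  ctx$path_memo[[key]] <- paths
  paths
}

# alignment cost of a pattern edge labeled `label` (governor image u,
# dependent image v): c(struct, label, dir), or NULL when disconnected.
ctx_align_cost <- function(ctx, u, v, label) {
  key <- paste0(u, "|", v, "|", label)
  hit <- ctx$cost_memo[[key]]
  if (!is.null(hit)) return(if (identical(hit, FALSE)) NULL else hit)
  paths <- ctx_shortest_node_paths(ctx, u, v)
  if (is.null(paths)) {
    ctx$cost_memo[[key]] <- FALSE
    return(NULL)
  }
  best <- NULL
  for (np in paths) {
    len <- length(np) - 1L
    if (len == 1L) {
      # parallel edges between u and v: pick the cheapest interpretation
      a <- ctx$adj[[as.character(u)]]
      sel <- a$other == v
      lc_dc <- cbind(as.integer(a$label[sel] != label),
                     as.integer(!a$out[sel]))
      # a differing-label edge oriented u->v still has consistent direction
      costs <- lc_dc[, 1] + lc_dc[, 2]
      k <- which.min(costs)
      lc <- lc_dc[k, 1]; dc <- lc_dc[k, 2]
    } else {
      has_label <- FALSE; has_consistent <- FALSE
      for (i in seq_len(len)) {
        x <- np[i]; y <- np[i + 1L]
        a <- ctx$adj[[as.character(x)]]
        sel <- a$other == y & a$label == label
        if (any(sel)) {
          has_label <- TRUE
          if (any(a$out[sel])) has_consistent <- TRUE
        }
      }
      lc <- as.integer(!has_label)
      dc <- as.integer(!has_consistent)
    }
    cand <- c(len - 1L, lc, dc)
    if (is.null(best) || (cand[2] + cand[3]) < (best[2] + best[3])) best <- cand
  }
  ctx$cost_memo[[key]] <- best
  best
}

#' Align one pattern edge against a sentence under a mapping
#'
#' Computes the per-edge contribution to the subgraph distance: the images of
#' the edge's endpoints are connected by a shortest undirected sentence path
#' (ties resolved toward the smallest label-plus-direction cost, then
#' lexicographic node order). `struct_c` is the path length minus one. For a
#' single-edge path, `label_c` flags a differing label and `dir_c` a
#' differing orientation. For a longer path, `label_c` flags the pattern
#' label being absent from the path and `dir_c` the absence of a
#' consistently oriented edge with that label.
#'
#' @param e single-row edge tibble from a pattern.
#' @param g a [sentence_graph()].
#' @param mapping an [asm_mapping()] with both endpoints mapped.
#' @return named numeric vector `c(struct_c, label_c, dir_c)`.
#' @export
edge_alignment <- function(e, g, mapping) {
  u <- mapping$pairs[[as.character(e$governor)]]
  v <- mapping$pairs[[as.character(e$dependent)]]
  if (is.null(u) || is.null(v)) abort("edge endpoint is not mapped")
  res <- ctx_align_cost(match_context(g), u, v, e$label)
  if (is.null(res)) abort("mapped endpoint images are disconnected")
  setNames(as.numeric(res), c("struct_c", "label_c", "dir_c"))
}

#' Construct a pattern-to-sentence mapping
#'
#' @param pairs named integer vector: names are pattern node indices (as
#'   strings), values sentence token indices; must be injective.
#' @param skipped integer vector of skipped (non-essential) pattern nodes.
#' @return object of class `asm_mapping`.
#' @export
asm_mapping <- function(pairs, skipped = integer()) {
  if (anyDuplicated(pairs)) abort("mapping is not injective")
  if (length(intersect(as.integer(names(pairs)), skipped))) {
    abort("a node cannot be both mapped and skipped")
  }
  structure(list(pairs = as.list(pairs), skipped = as.integer(skipped)),
            class = "asm_mapping")
}

#' Subgraph distance of a mapping
#'
#' Sums the per-edge alignment costs over all pattern edges whose endpoints
#' are both mapped; edges touching a skipped node contribute nothing except
#' through the node-skipping penalty `nodeDist = |skipped| / |V_r|`. With no
#' skipped nodes the value equals the original three-component distance.
#'
#' @param p an [event_pattern()].
#' @param g a [sentence_graph()].
#' @param mapping an [asm_mapping()]; every essential node must be mapped,
#'   and `mapped + skipped` must cover all pattern nodes.
#' @param weights a [distance_weights()].
#' @return an `asm_match` object with components `struct_d`, `label_d`,
#'   `dir_d`, `node_d` and `total` (infinite if any edge alignment fails).
#' @export
subgraph_distance <- function(p, g, mapping, weights = distance_weights(),
                              .ctx = NULL) {
  mapped <- as.integer(names(mapping$pairs))
  if (!all(p$essential %in% mapped)) abort("an essential node is unmapped")
  if (!setequal(c(mapped, mapping$skipped), p$nodes$index)) {
    abort("mapped and skipped nodes must partition the pattern nodes")
  }
  ctx <- if (is.null(.ctx)) match_context(g) else .ctx
  comp <- c(struct_d = 0, label_d = 0, dir_d = 0)
  failed <- FALSE
  for (k in seq_len(nrow(p$edges))) {
    gv <- p$edges$governor[k]; dp <- p$edges$dependent[k]
    if (gv %in% mapping$skipped || dp %in% mapping$skipped) next
    cost <- ctx_align_cost(ctx, mapping$pairs[[as.character(gv)]],
                           mapping$pairs[[as.character(dp)]], p$edges$label[k])
    if (is.null(cost)) { failed <- TRUE; break }
    comp <- comp + cost
  }
  node_d <- length(mapping$skipped) / nrow(p$nodes)
  total <- if (failed) Inf else {
    weights$w_s * comp[["struct_d"]] + weights$w_l * comp[["label_d"]] +
      weights$w_d * comp[["dir_d"]] + weights$w_n * node_d
  }
  structure(
    list(pattern_id = p$pattern_id, mapping = mapping,
         struct_d = if (failed) Inf else comp[["struct_d"]],
         label_d = if (failed) Inf else comp[["label_d"]],
         dir_d = if (failed) Inf else comp[["dir_d"]],
         node_d = node_d, total = total),
    class = "asm_match")
}

#' @export
print.asm_match <- function(x, ...) {
  img <- paste(names(x$mapping$pairs), unlist(x$mapping$pairs), sep = "->",
               collapse = " ")
  cat("<asm_match ", x$pattern_id, " total=", format(x$total), " [s=",
      x$struct_d, " l=", x$label_d, " d=", x$dir_d, " n=",
      format(x$node_d), "] ", img,
      if (length(x$mapping$skipped)) paste0(" skip={",
        paste(x$mapping$skipped, collapse = ","), "}") else "",
      ">\n", sep = "")
  invisible(x)
}

match_image_key <- function(m, essential) {
  paste(vapply(as.character(sort(essential)),
               function(k) m$mapping$pairs[[k]], integer(1)), collapse = ",")
}

match_full_key <- function(m, p) {
  paste(vapply(as.character(p$nodes$index), function(k) {
    v <- m$mapping$pairs[[k]]
    if (is.null(v)) "-" else sprintf("%05d", v)
  }, character(1)), collapse = ",")
}

# keep, per distinct essential-node image, the single best match:
# minimal total, then fewest skipped nodes, then lexicographic image.
reduce_matches <- function(matches, p) {
  if (!length(matches)) return(list())
  keys <- vapply(matches, match_image_key, character(1), essential = p$essential)
  out <- list()
  for (key in sort(unique(keys))) {
    grp <- matches[keys == key]
    tot <- vapply(grp, `[[`, numeric(1), "total")
    grp <- grp[tot <= min(tot) + 1e-9]
    nsk <- vapply(grp, function(m) length(m$mapping$skipped), integer(1))
    grp <- grp[nsk == min(nsk)]
    fk <- vapply(grp, match_full_key, character(1), p = p)
    out[[length(out) + 1L]] <- grp[[order(fk)[1]]]
  }
  out
}

#' Find all approximate matches of a pattern in a sentence
#'
#' Exhaustively searches injective mappings of the pattern nodes onto
#' compatible sentence tokens (branch-and-bound pruning on the running
#' distance, which cannot change the result because all component
#' contributions are non-negative). With `allow_skip = TRUE`, non-essential
#' pattern nodes may be left unmapped at a penalty of `w_n / |V_r|` each.
#' For every distinct image of the essential nodes only the minimal-distance
#' match is returned (ties: fewest skipped nodes, then lexicographic image).
#'
#' @param p an [event_pattern()].
#' @param g a [sentence_graph()].
#' @param weights a [distance_weights()].
#' @param t distance threshold (>= 0); only matches with `total <= t` are
#'   returned.
#' @param policy a [match_policy()].
#' @param allow_skip logical; `FALSE` recovers the original fully injective
#'   matching.
#' @return list of `asm_match` objects (possibly empty).
#' @export
find_matches <- function(p, g, weights = distance_weights(), t = 0,
                         policy = match_policy(), allow_skip = FALSE) {
  stopifnot(t >= 0)
  cand <- node_candidates(p, g, policy)
  if (any(lengths(cand[as.character(p$essential)]) == 0)) return(list())
  ctx <- match_context(g)
  n <- nrow(p$nodes)
  order_nodes <- p$nodes$index
  skip_cost <- weights$w_n / n
  results <- list()
  assign_map <- list()
  used <- integer()
  skipped <- integer()
  comp <- c(s = 0, l = 0, d = 0)

  edge_partners <- lapply(order_nodes, function(v) {
    k <- which(p$edges$governor == v | p$edges$dependent == v)
    list(rows = k, gov = p$edges$governor[k], dep = p$edges$dependent[k],
         lab = p$edges$label[k])
  })
  names(edge_partners) <- as.character(order_nodes)

  running_total <- function(cm, nsk) {
    weights$w_s * cm[["s"]] + weights$w_l * cm[["l"]] +
      weights$w_d * cm[["d"]] + weights$w_n * nsk / n
  }

  dfs <- function(i) {
    if (i > n) {
      total <- running_total(comp, length(skipped))
      if (total <= t + 1e-9) {
        m <- structure(list(
          pattern_id = p$pattern_id,
          mapping = asm_mapping(setNames(unlist(assign_map),
                                         names(assign_map)), skipped),
          struct_d = comp[["s"]], label_d = comp[["l"]], dir_d = comp[["d"]],
          node_d = length(skipped) / n, total = total), class = "asm_match")
        results[[length(results) + 1L]] <<- m
      }
      return()
    }
    v <- order_nodes[i]
    vk <- as.character(v)
    ep <- edge_partners[[vk]]
    for (s in cand[[vk]]) {
      if (s %in% used) next
      delta <- c(s = 0, l = 0, d = 0)
      ok <- TRUE
      for (j in seq_along(ep$rows)) {
        other <- if (ep$gov[j] == v) ep$dep[j] else ep$gov[j]
        so <- assign_map[[as.character(other)]]
        if (is.null(so)) next
        uu <- if (ep$gov[j] == v) s else so
        vv <- if (ep$gov[j] == v) so else s
        cost <- ctx_align_cost(ctx, uu, vv, ep$lab[j])
        if (is.null(cost)) { ok <- FALSE; break }
        delta <- delta + setNames(cost, c("s", "l", "d"))
      }
      if (!ok) next
      newc <- comp + delta
      if (running_total(newc, length(skipped)) > t + 1e-9) next
      assign_map[[vk]] <<- s
      used <<- c(used, s)
      old <- comp; comp <<- newc
      dfs(i + 1L)
      comp <<- old
      used <<- used[-length(used)]
      assign_map[[vk]] <<- NULL
    }
    if (allow_skip && !(v %in% p$essential)) {
      if (running_total(comp, length(skipped) + 1L) <= t + 1e-9) {
        skipped <<- c(skipped, v)
        dfs(i + 1L)
        skipped <<- skipped[-length(skipped)]
      }
    }
  }
  dfs(1L)
  reduce_matches(results, p)
}

node_candidates <- function(p, g, policy) {
  sel <- !g$tokens$absorbed
  out <- lapply(seq_len(nrow(p$nodes)), function(i) {
    ok <- vapply(which(sel), function(j) {
      node_match(p$nodes[i, ], g$tokens[j, ], policy)
    }, logical(1))
    g$tokens$index[which(sel)[ok]]
  })
  names(out) <- as.character(p$nodes$index)
  out
}

#' Brute-force reference matcher
#'
#' Enumerates every admissible skipped subset and every injective assignment
#' of the remaining pattern nodes, computes the full subgraph distance for
#' each, and applies the same per-essential-image reduction as
#' [find_matches()]. Used as the exhaustive test oracle; guarded to small
#' patterns.
#'
#' @inheritParams find_matches
#' @return list of `asm_match` objects.
#' @export
brute_force_matches <- function(p, g, weights = distance_weights(), t = 0,
                                policy = match_policy(), allow_skip = FALSE) {
  if (nrow(p$nodes) > 10) abort("brute_force_matches is guarded to <= 10 nodes")
  stopifnot(t >= 0)
  cand <- node_candidates(p, g, policy)
  nonessential <- setdiff(p$nodes$index, p$essential)
  subsets <- list(integer())
  if (allow_skip && length(nonessential)) {
    subsets <- unlist(lapply(0:length(nonessential), function(k) {
      if (k == 0) return(list(integer()))
      if (length(nonessential) == 1) return(list(nonessential))
      utils::combn(nonessential, k, simplify = FALSE)
    }), recursive = FALSE)
  }
  results <- list()
  ctx <- match_context(g)
  for (sk in subsets) {
    mapped_nodes <- setdiff(p$nodes$index, sk)
    lists <- cand[as.character(mapped_nodes)]
    if (any(lengths(lists) == 0)) next
    enumerate <- function(i, acc) {
      if (i > length(mapped_nodes)) {
        m <- subgraph_distance(
          p, g, asm_mapping(setNames(acc, as.character(mapped_nodes)), sk),
          weights, .ctx = ctx)
        if (m$total <= t + 1e-9) results[[length(results) + 1L]] <<- m
        return()
      }
      for (s in lists[[i]]) {
        if (s %in% acc) next
        enumerate(i + 1L, c(acc, s))
      }
    }
    enumerate(1L, integer())
  }
  reduce_matches(results, p)
}

#' Serialize matches as JSON lines
#'
#' @param matches list of `asm_match` objects.
#' @return character vector, one JSON object per match.
#' @export
matches_to_json <- function(matches) {
  vapply(matches, function(m) {
    jsonlite::toJSON(list(
      pattern_id = m$pattern_id,
      image = m$mapping$pairs,
      skipped = m$mapping$skipped,
      struct_d = m$struct_d, label_d = m$label_d, dir_d = m$dir_d,
      node_d = m$node_d, total = m$total), auto_unbox = TRUE)
  }, character(1))
}
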