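#' Task configuration
#'
#' Bundles the event type inventory, the per-type batch distance thresholds,
#' the distance weights and the matching options. The full parameter vector
#' (one threshold per event type plus the active distance weights) is
#' exposed by [parameter_vector()].
#'
#' @param event_types character vector of event type names (ordered).
#' @param thresholds named numeric vector of per-type thresholds t_e;
#'   unnamed scalar recycles to all types.
#' @param weights a [distance_weights()].
#' @param allow_skip logical; enables non-essential node skipping (and adds
#'   `w_n` to the parameter vector).
#' @param policy a [match_policy()].
#' @param max_rounds iteration cap for bottom-up extraction.
#' @return object of class `task_config`.
#' @export
task_config <- function(event_types, thresholds = 0,
                        weights = distance_weights(), allow_skip = FALSE,
                        policy = match_policy(), max_rounds = 10L) {
  if (length(thresholds) == 1 && is.null(names(thresholds))) {
    thresholds <- setNames(rep(thresholds, length(event_types)), event_types)
  }
  if (!all(event_types %in% names(thresholds))) {
    abort("every event type needs a threshold")
  }
  if (any(thresholds < 0)) abort("thresholds must be non-negative")
  structure(list(event_types = event_types,
                 thresholds = thresholds[event_types], weights = weights,
                 allow_skip = allow_skip, policy = policy,
                 max_rounds = as.integer(max_rounds)),
            class = "task_config")
}

#' Flatten a task configuration to its named parameter vector
#'
#' One distance threshold per event type, followed by the distance weights in
#' use: `w_s`, `w_l`, `w_d`, plus `w_n` when node skipping is enabled. A
#' 13-type configuration without skipping therefore exposes 16 parameters; a
#' 40-type one exposes 43.
#'
#' @param cfg a [task_config()].
#' @return tibble with columns `name` and `value`.
#' @export
parameter_vector <- function(cfg) {
  t_names <- if (length(cfg$event_types)) {
    paste0("t_", cfg$event_types)
  } else character(0)
  nm <- c(t_names, "w_s", "w_l", "w_d", if (cfg$allow_skip) "w_n")
  val <- c(unname(cfg$thresholds), cfg$weights$w_s, cfg$weights$w_l,
           cfg$weights$w_d, if (cfg$allow_skip) cfg$weights$w_n)
  tibble(name = nm, value = val)
}

candidate_signature <- function(doc_id, sentence, type, trigger_tokens, args) {
  akey <- if (nrow(args)) {
    paste(sort(paste(args$role, args$kind, args$target, sep = "=")),
          collapse = ";")
  } else ""
  paste0(doc_id, "|", sentence, "|", type, "|T:",
         paste(sort(trigger_tokens), collapse = ","), "|", akey)
}

new_candidate <- function(doc_id, sentence, type, trigger_tokens, args,
                          pattern_id, distance) {
  sig <- candidate_signature(doc_id, sentence, type, trigger_tokens, args)
  list(sig = sig, doc_id = doc_id, sentence = sentence, event_type = type,
       trigger_tokens = sort(trigger_tokens), args = args,
       pattern_id = pattern_id, distance = distance,
       producers = tibble(pattern_id = pattern_id, distance = distance))
}

candidate_set <- function(candidates = list()) {
  structure(list(candidates = candidates), class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate_set: ", length(x$candidates), " candidate event(s)>\n",
      sep = "")
  invisible(x)
}

add_candidate <- function(store, cand) {
  old <- store$candidates[[cand$sig]]
  if (is.null(old)) {
    store$candidates[[cand$sig]] <- cand
    attr(store, "new") <- TRUE
    return(store)
  }
  producers <- unique(bind_rows(old$producers, cand$producers))
  old$producers <- producers
  best <- which.min(producers$distance)
  old$pattern_id <- producers$pattern_id[best]
  old$distance <- producers$distance[best]
  store$candidates[[cand$sig]] <- old
  attr(store, "new") <- FALSE
  store
}

# turn an asm match into zero or more candidates, combining over the
# already-extracted events available at each sub-event node image.
match_to_candidates <- function(doc, g, p, m, existing) {
  arg_bind <- p$bindings[p$bindings$kind != "trigger", ]
  trig_img <- sort(unlist(m$mapping$pairs[as.character(
    p$bindings$node[p$bindings$kind == "trigger"])]))
  per_arg <- vector("list", nrow(arg_bind))
  for (k in seq_len(nrow(arg_bind))) {
    img <- m$mapping$pairs[[as.character(arg_bind$node[k])]]
    if (arg_bind$kind[k] == "entity") {
      eid <- doc$entities$id[doc$entities$sentence == g$sentence_id &
                               doc$entities$head_token == img]
      if (!length(eid)) return(list())
      per_arg[[k]] <- lapply(eid[1], function(e) {
        list(kind = "entity", target = e, type = NA_character_)
      })
    } else {
      subs <- keep(existing, function(cd) {
        cd$sentence == g$sentence_id && img %in% cd$trigger_tokens
      })
      if (!length(subs)) return(list())
      per_arg[[k]] <- lapply(unname(subs), function(cd) {
        list(kind = "event", target = cd$sig, type = cd$event_type)
      })
    }
  }
  combos <- expand.grid(lapply(per_arg, seq_along), KEEP.OUT.ATTRS = FALSE)
  out <- list()
  for (r in seq_len(nrow(combos))) {
    args <- tibble(
      role = arg_bind$role,
      kind = arg_bind$kind,
      target = vapply(seq_len(nrow(arg_bind)), function(k) {
        per_arg[[k]][[combos[r, k]]]$target
      }, character(1)),
      subevent_type = vapply(seq_len(nrow(arg_bind)), function(k) {
        ty <- per_arg[[k]][[combos[r, k]]]$type
        if (is.na(ty)) "" else ty
      }, character(1)))
    out[[length(out) + 1L]] <- new_candidate(
      doc$doc_id, g$sentence_id, p$event_type, trig_img,
      args[, c("role", "kind", "target", "subevent_type")],
      p$pattern_id, m$total)
  }
  out
}

pattern_threshold <- function(p, cfg, thresholds) {
  if (!is.null(thresholds)) {
    if (length(thresholds) == 1 && is.null(names(thresholds))) {
      return(as.numeric(thresholds))
    }
    if (p$pattern_id %in% names(thresholds)) {
      return(as.numeric(thresholds[[p$pattern_id]]))
    }
  }
  if (!is.na(p$threshold)) return(p$threshold)
  if (!is.null(cfg) && p$event_type %in% names(cfg$thresholds)) {
    return(unname(cfg$thresholds[[p$event_type]]))
  }
  0
}

#' Extract candidate events from a document
#'
#' Iterative bottom-up extraction: patterns whose arguments are all entities
#' (lower-order) are matched first; higher-order patterns then fire whenever
#' every sub-event node's image is the trigger token of an already-extracted
#' event of any type, producing one candidate per combination when several
#' events share a trigger token. Iteration stops when no further candidates
#' are produced, or after `max_rounds` (a warning is issued and the partial
#' output returned). Output is deduplicated by recursive structural equality;
#' each retained candidate records every (pattern, distance) pair that
#' produced it.
#'
#' @param doc an anonymized [standoff_document()].
#' @param patterns list of [event_pattern()].
#' @param cfg a [task_config()] (supplies weights, policy, per-type
#'   thresholds, skipping).
#' @param thresholds optional override: a single numeric applied to every
#'   pattern (the cached-extraction mode) or a named vector by pattern id.
#' @return a `candidate_set`.
#' @export
extract_events <- function(doc, patterns, cfg = NULL, thresholds = NULL) {
  weights <- if (!is.null(cfg)) cfg$weights else distance_weights()
  policy <- if (!is.null(cfg)) cfg$policy else match_policy()
  allow_skip <- if (!is.null(cfg)) cfg$allow_skip else FALSE
  max_rounds <- if (!is.null(cfg)) cfg$max_rounds else 10L
  lower <- discard(patterns, is_higher_order)
  higher <- keep(patterns, is_higher_order)
  store <- candidate_set()

  # round 0: lower-order patterns
  for (p in lower) {
    t_p <- pattern_threshold(p, cfg, thresholds)
    for (g in doc$sentences) {
      for (m in find_matches(p, g, weights, t_p, policy, allow_skip)) {
        for (cd in match_to_candidates(doc, g, p, m, list())) {
          store <- add_candidate(store, cd)
        }
      }
    }
  }

  # graph matching for higher-order patterns is independent of the candidate
  # pool, so match once and iterate only the combination step.
  higher_matches <- list()
  for (p in higher) {
    t_p <- pattern_threshold(p, cfg, thresholds)
    for (g in doc$sentences) {
      ms <- find_matches(p, g, weights, t_p, policy, allow_skip)
      if (length(ms)) {
        higher_matches[[length(higher_matches) + 1L]] <-
          list(p = p, g = g, ms = ms)
      }
    }
  }
  round <- 0L
  repeat {
    round <- round + 1L
    if (round > max_rounds) {
      warn("extraction did not reach a fixpoint within max_rounds")
      break
    }
    grew <- FALSE
    for (h in higher_matches) {
      for (m in h$ms) {
        for (cd in match_to_candidates(doc, h$g, h$p, m, store$candidates)) {
          store <- add_candidate(store, cd)
          if (isTRUE(attr(store, "new"))) grew <- TRUE
        }
      }
    }
    if (!grew) break
  }
  store
}

#' Extract candidate events from a corpus
#'
#' @param docs list of anonymized documents.
#' @inheritParams extract_events
#' @return a merged `candidate_set` across documents.
#' @export
extract_corpus <- function(docs, patterns, cfg = NULL, thresholds = NULL) {
  out <- candidate_set()
  for (doc in docs) {
    cs <- extract_events(doc, patterns, cfg, thresholds)
    out$candidates <- c(out$candidates, cs$candidates)
  }
  out
}

#' Re-filter cached candidates under a threshold vector
#'
#' A candidate is valid iff at least one of its producing (pattern, distance)
#' pairs satisfies `distance <= threshold[pattern]` and all of its sub-event
#' arguments are recursively valid. When candidate generation was exhaustive
#' at the maximal threshold this equals re-running [extract_events()] at the
#' given thresholds (the single-matching efficiency contract used by the
#' threshold learners).
#'
#' @param cands a `candidate_set` produced at the maximal threshold.
#' @param thresholds named numeric vector by pattern id.
#' @param missing `"error"` (default) to reject candidates whose producing
#'   pattern has no threshold entry, or `"drop"` to treat such producers as
#'   removed patterns (used by pattern-set optimization).
#' @return the valid `candidate_set` subset.
#' @export
filter_candidates <- function(cands, thresholds, missing = c("error", "drop")) {
  missing <- match.arg(missing)
  memo <- new.env(parent = emptyenv())
  valid <- function(sig) {
    hit <- memo[[sig]]
    if (!is.null(hit)) return(hit)
    cd <- cands$candidates[[sig]]
    pr <- cd$producers
    known <- pr$pattern_id %in% names(thresholds)
    if (missing == "error" && any(!known)) {
      abort(paste0("no threshold for pattern ",
                   pr$pattern_id[!known][1]))
    }
    ok_prod <- any(known &
                     pr$distance <= thresholds[pr$pattern_id] + 1e-9,
                   na.rm = TRUE)
    res <- ok_prod
    if (res) {
      for (k in which(cd$args$kind == "event")) {
        if (!valid(cd$args$target[k])) { res <- FALSE; break }
      }
    }
    memo[[sig]] <- res
    res
  }
  keep_sigs <- names(cands$candidates)[vapply(names(cands$candidates), valid,
                                              logical(1))]
  candidate_set(cands$candidates[keep_sigs])
}

arg_keys <- function(cd) {
  paste(cd$args$role, cd$args$kind, cd$args$target, sep = "=")
}

candidate_group_key <- function(cd) {
  paste(cd$doc_id, cd$sentence, cd$event_type,
        paste(cd$trigger_tokens, collapse = ","))
}

# recursive partial-view relation: a is a partial view of b when both share
# document, sentence, type and trigger, and a's arguments inject into b's
# with equal role and kind, entity targets equal, and event targets
# recursively partial views. Distinct candidates cannot be mutual partial
# views, so dropping any strictly subsumed candidate is well defined.
candidate_subsumes <- function(cl, a, b, memo = new.env(parent = emptyenv())) {
  if (identical(a, b)) return(TRUE)
  key <- paste0(a, "\r", b)
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  A <- cl[[a]]; B <- cl[[b]]
  res <- FALSE
  if (!is.null(A) && !is.null(B) &&
      candidate_group_key(A) == candidate_group_key(B) &&
      nrow(A$args) <= nrow(B$args)) {
    usedB <- logical(nrow(B$args))
    bt <- function(i) {
      if (i > nrow(A$args)) return(TRUE)
      for (j in which(!usedB)) {
        if (A$args$role[i] == B$args$role[j] &&
            A$args$kind[i] == B$args$kind[j]) {
          ok <- if (A$args$kind[i] == "entity") {
            A$args$target[i] == B$args$target[j]
          } else {
            candidate_subsumes(cl, A$args$target[i], B$args$target[j], memo)
          }
          if (ok) {
            usedB[j] <<- TRUE
            if (bt(i + 1L)) { usedB[j] <<- FALSE; return(TRUE) }
            usedB[j] <<- FALSE
          }
        }
      }
      FALSE
    }
    res <- bt(1L)
  }
  memo[[key]] <- res
  res
}

#' Consolidate candidates into reported events
#'
#' Individual-path patterns deliberately extract partial views of
#' multi-argument events; union patterns re-assemble them. Finalization
#' drops any candidate that is a strict partial view of another candidate
#' with the same document, sentence, type and trigger tokens — including
#' recursively, when the only difference is that a sub-event argument is
#' itself a partial view (joint inference takes precedence over partial
#' paths).
#'
#' @param cands a `candidate_set` (typically already threshold-filtered).
#' @return list of candidate events, the reported extraction output.
#' @export
finalize_events <- function(cands) {
  cl <- cands$candidates
  if (!length(cl)) return(list())
  sigs <- names(cl)
  keys <- vapply(cl, candidate_group_key, character(1))
  memo <- new.env(parent = emptyenv())
  keep <- rep(TRUE, length(cl))
  for (i in seq_along(cl)) {
    for (j in which(keys == keys[i])) {
      if (j != i && candidate_subsumes(cl, sigs[i], sigs[j], memo)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  unname(cl[keep])
}

#' Gold-standard event signatures of a document
#'
#' @param doc a [standoff_document()] with events.
#' @return character vector of recursive structural signatures.
#' @export
gold_signatures <- function(doc) {
  sigs <- character()
  memo <- list()
  sig_of <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    ev <- doc$events[[id]]
    g <- doc$sentences[[ev$sentence]]
    absorbed <- g$tokens$index[g$tokens$absorbed]
    trig <- setdiff(ev$trigger_tokens, absorbed)
    args <- tibble(
      role = normalize_role(ev$args$role),
      kind = ifelse(startsWith(ev$args$target, "T"), "entity", "event"),
      target = vapply(ev$args$target, function(tg) {
        if (startsWith(tg, "T")) tg else sig_of(tg)
      }, character(1)))
    s <- candidate_signature(doc$doc_id, ev$sentence, ev$type, trig, args)
    memo[[id]] <<- s
    s
  }
  for (id in names(doc$events)) sigs <- c(sigs, sig_of(id))
  unique(sigs)
}

#' Strict evaluation of predicted against gold events
#'
#' Two events are equal iff they have the same type, the same trigger token
#' set and the same argument roles with recursively equal targets (entities
#' by identifier, sub-events structurally). Recall is `tp / (tp + fn)`,
#' precision `tp / (tp + fp)` (0 when the denominator is 0) and the F-score
#' their harmonic mean.
#'
#' @param pred predicted events: a list from [finalize_events()], a
#'   `candidate_set`, or a character vector of signatures.
#' @param gold gold events: a document, a list of documents, or a character
#'   vector of signatures.
#' @return a tibble with tp, fp, fn, recall, precision, f_score.
#' @export
evaluate_strict <- function(pred, gold) {
  pred_sigs <- if (is.character(pred)) pred
    else if (inherits(pred, "candidate_set")) {
      vapply(finalize_events(pred), `[[`, "", "sig")
    } else vapply(pred, `[[`, "", "sig")
  gold_sigs <- if (is.character(gold)) gold
    else if (inherits(gold, "standoff_document")) gold_signatures(gold)
    else unlist(lapply(gold, gold_signatures))
  pred_sigs <- unique(pred_sigs); gold_sigs <- unique(gold_sigs)
  tp <- length(intersect(pred_sigs, gold_sigs))
  fp <- length(pred_sigs) - tp
  fn <- length(gold_sigs) - tp
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f <- if (recall + precision > 0) {
    2 * recall * precision / (recall + precision)
  } else 0
  tibble(tp = tp, fp = fp, fn = fn, recall = recall, precision = precision,
         f_score = f)
}

#' Attach extracted events to a document
#'
#' Converts finalized candidates for one document into standoff event
#' mentions (E identifiers assigned bottom-up) so the result can be
#' serialized with [write_a2()].
#'
#' @param doc the (anonymized) source document.
#' @param finalized list of candidates from [finalize_events()].
#' @return the document with its `events` replaced by the predictions.
#' @export
candidates_to_doc_events <- function(doc, finalized) {
  mine <- keep(finalized, function(cd) cd$doc_id == doc$doc_id)
  ids <- character(); n <- 0L
  events <- list()
  assign_id <- function(cd) {
    if (cd$sig %in% names(ids)) return(ids[[cd$sig]])
    # children first
    targets <- vapply(seq_len(nrow(cd$args)), function(k) {
      if (cd$args$kind[k] == "entity") return(cd$args$target[k])
      child <- keep(mine, function(x) x$sig == cd$args$target[k])
      if (!length(child)) {
        abort(paste0("finalized set lacks sub-event ", cd$args$target[k]))
      }
      assign_id(child[[1]])
    }, character(1))
    n <<- n + 1L
    id <- paste0("E", n)
    ids[[cd$sig]] <<- id
    events[[id]] <<- list(
      id = id, type = cd$event_type, sentence = cd$sentence,
      trigger_tokens = cd$trigger_tokens,
      args = tibble(role = cd$args$role, target = targets))
    id
  }
  # ensure referenced sub-events exist even if subsumption removed them:
  # they are always in the finalized list because a valid parent requires
  # valid children, and children with distinct triggers are never subsumed
  # by the parent.
  for (cd in mine) assign_id(cd)
  doc$events <- events
  check_event_references(doc)
  doc
}
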