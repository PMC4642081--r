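#' Build a distributional similarity model from dependency contexts
#'
#' Each word (keyed by lemma plus POS tag) is represented by a sparse vector
#' over its first-level dependency contexts: for a dependent token the
#' feature is `"governorLemma→label"`, for a governor token
#' `"dependentLemma←label"`. Feature values are pointwise mutual information
#' in ratio form, `mi = F_c(w) * N / (F(w) * F(c))` (a `log` form, floored
#' at zero, is available), multiplied by the Lin discount
#' `F_c(w)/(F_c(w)+1) * min(F(w),F(c))/(min(F(w),F(c))+1)` to counter the
#' bias toward rare words, and finally scaled into `[0, 1)` via
#' `lambda * mi / (1 + lambda * mi)`. Contexts whose corpus frequency is not
#' above `min_context_freq` are dropped.
#'
#' @param corpus list of [sentence_graph()] objects with lemma, POS and
#'   dependency edges.
#' @param lambda_scale scaling constant (default 0.01).
#' @param min_context_freq contexts must appear more than this many times
#'   (default 5).
#' @param form `"ratio"` (default) or `"log"`.
#' @param depth dependency context depth; 1 (default) uses direct
#'   governor/dependent contexts, 2 additionally walks one edge further with
#'   composed labels.
#' @return object of class `dsm_model`.
#' @export
build_dsm <- function(corpus, lambda_scale = 0.01, min_context_freq = 5L,
                      form = c("ratio", "log"), depth = 1L) {
  form <- match.arg(form)
  if (!length(corpus)) abort("empty corpus")
  words <- character(); feats <- character()
  for (g in corpus) {
    tok <- g$tokens
    key <- paste0(tok$lemma, "/", tok$pos)
    lemma_of <- setNames(tok$lemma, as.character(tok$index))
    key_of <- setNames(key, as.character(tok$index))
    e <- g$edges
    if (!nrow(e)) next
    gv <- as.character(e$governor); dp <- as.character(e$dependent)
    # dependent side: "governorLemma→label"; governor side: "depLemma←label"
    words <- c(words, key_of[dp], key_of[gv])
    feats <- c(feats, paste0(lemma_of[gv], "→", e$label),
               paste0(lemma_of[dp], "←", e$label))
    if (depth >= 2L) {
      for (k in seq_len(nrow(e))) {
        up <- which(e$dependent == e$governor[k])
        for (j in up) {
          words <- c(words, key_of[[as.character(e$dependent[k])]])
          feats <- c(feats, paste0(lemma_of[[as.character(e$governor[j])]],
                                   "→", e$label[j], "→", e$label[k]))
        }
      }
    }
  }
  if (!length(words)) abort("corpus has no dependency edges")
  inc <- tibble(word = unname(words), feature = unname(feats))
  cnt <- dplyr::count(inc, .data$word, .data$feature, name = "f_wc")
  f_w <- dplyr::count(inc, .data$word, name = "f_w")
  f_c <- dplyr::count(inc, .data$feature, name = "f_c")
  n_total <- nrow(inc)
  cnt <- left_join(cnt, f_w, by = "word")
  cnt <- left_join(cnt, f_c, by = "feature")
  cnt <- cnt[cnt$f_c > min_context_freq, , drop = FALSE]
  raw <- cnt$f_wc * n_total / (cnt$f_w * cnt$f_c)
  if (form == "log") raw <- pmax(log(raw), 0)
  disc <- (cnt$f_wc / (cnt$f_wc + 1)) *
    (pmin(cnt$f_w, cnt$f_c) / (pmin(cnt$f_w, cnt$f_c) + 1))
  mi <- raw * disc
  cnt$value <- lambda_scale * mi / (1 + lambda_scale * mi)
  cnt <- cnt[cnt$value > 0, , drop = FALSE]
  vectors <- lapply(split(cnt, cnt$word), function(d) {
    setNames(d$value, d$feature)[order(d$feature)]
  })
  structure(list(vectors = vectors, lambda_scale = lambda_scale,
                 min_context_freq = as.integer(min_context_freq),
                 form = form, n_total = n_total),
            class = "dsm_model")
}

#' @export
print.dsm_model <- function(x, ...) {
  cat("<dsm_model: ", length(x$vectors), " words, lambda=", x$lambda_scale,
      ", min context freq ", x$min_context_freq, ">\n", sep = "")
  invisible(x)
}

#' Cosine similarity of two sparse feature vectors
#'
#' @param a,b named non-negative numeric vectors.
#' @return number in `[0, 1]`; 0 when either vector is all-zero.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  shared <- intersect(names(a), names(b))
  if (!length(shared)) return(0)
  sum(a[shared] * b[shared]) / (na * nb)
}

#' Top-M most similar words
#'
#' Ranks every other word in the model by cosine similarity to `w`
#' (ties broken lexicographically) and returns the best `m`.
#'
#' @param model a [dsm_model()].
#' @param w word key (`"lemma/POS"`).
#' @param m number of neighbours; 0 gives an empty result.
#' @return tibble with columns `word` and `similarity`; empty when `w` is
#'   unknown.
#' @export
top_m_similar <- function(model, w, m) {
  empty <- tibble(word = character(), similarity = numeric())
  if (m <= 0 || is.null(model$vectors[[w]])) return(empty)
  others <- setdiff(names(model$vectors), w)
  if (!length(others)) return(empty)
  sims <- vapply(others, function(o) {
    cosine_similarity(model$vectors[[w]], model$vectors[[o]])
  }, numeric(1))
  ord <- order(-sims, others)
  take <- head(ord, m)
  tibble(word = others[take], similarity = unname(sims[take]))
}

# lemmas of the top-M neighbours of (lemma, pos); used during node matching.
dsm_similar_lemmas <- function(model, lemma, pos, m) {
  key <- paste0(lemma, "/", pos)
  if (is.null(model$vectors[[key]])) {
    # fall back to any key with this lemma and the same relaxed POS
    keys <- names(model$vectors)
    lem <- sub("/[^/]*$", "", keys)
    ps <- sub("^.*/", "", keys)
    hit <- keys[lem == lemma & relaxed_pos(ps) == relaxed_pos(pos)]
    if (!length(hit)) return(character())
    key <- sort(hit)[1]
  }
  top <- top_m_similar(model, key, m)
  unique(sub("/[^/]*$", "", top$word))
}

#' Generatively expand patterns with distributional neighbours
#'
#' For each substitutable pattern node (all non-entity nodes, or trigger
#' nodes only) and each of the node's top-M most similar words, emits one
#' copy of the pattern with that single lemma substituted. Originals are
#' retained and the result is deduplicated.
#'
#' @param patterns list of [event_pattern()].
#' @param model a [dsm_model()].
#' @param m number of neighbours per node (>= 1 for any expansion).
#' @param scope `"all"` tokens or `"trigger"` tokens only.
#' @return list of patterns (originals plus deduplicated copies).
#' @export
expand_patterns <- function(patterns, model, m, scope = c("all", "trigger")) {
  scope <- match.arg(scope)
  out <- patterns
  for (p in patterns) {
    eligible <- p$nodes$index[!p$nodes$is_entity]
    if (scope == "trigger") {
      trig <- p$bindings$node[p$bindings$kind == "trigger"]
      eligible <- intersect(eligible, trig)
    }
    k <- 0L
    for (idx in eligible) {
      i <- match(idx, p$nodes$index)
      sims <- dsm_similar_lemmas(model, p$nodes$lemma[i], p$nodes$pos[i], m)
      for (s in sims) {
        if (identical(s, p$nodes$lemma[i])) next
        q <- p
        q$nodes$lemma[i] <- s
        q$nodes$surface[i] <- s
        k <- k + 1L
        q$pattern_id <- paste0(p$pattern_id, "_dsm", k)
        out[[length(out) + 1L]] <- q
      }
    }
  }
  dedup_patterns(out)
}

#' Serialize a DSM to sorted JSON lines
#'
#' One line per (word, feature, value) triple, sorted, for diff-able tests.
#'
#' @param model a [dsm_model()].
#' @param path optional output file.
#' @return character vector of JSON lines.
#' @export
write_dsm <- function(model, path = NULL) {
  lines <- character()
  for (w in sort(names(model$vectors))) {
    v <- model$vectors[[w]]
    for (f in sort(names(v))) {
      lines <- c(lines, jsonlite::toJSON(
        list(word = w, feature = f, value = v[[f]]), auto_unbox = TRUE,
        digits = NA))
    }
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
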