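#' Construct a standoff-annotated document
#'
#' A document bundles the raw text, one [sentence_graph()] per sentence,
#' entity mentions (T annotations) and event mentions (E annotations).
#' Events must live inside a single sentence: the trigger and every argument
#' (recursively, for event arguments) must resolve to the same sentence.
#'
#' @param doc_id document identifier.
#' @param text full document text; sentences are newline-separated.
#' @param sentences list of [sentence_graph()], in textual order.
#' @param entities tibble with columns `id`, `type`, `char_start`, `char_end`,
#'   `sentence`, `head_token` and a list column `tokens` of member indices.
#' @param events named list of event mentions; each has `id`, `type`,
#'   `sentence`, `trigger_tokens` (sentence-local indices) and `args`,
#'   a tibble with columns `role` and `target` (a T or E identifier).
#' @return an object of class `standoff_document`.
#' @export
standoff_document <- function(doc_id, text, sentences,
                              entities = empty_entities(), events = list()) {
  names(sentences) <- vapply(sentences, `[[`, "", "sentence_id")
  if (length(events)) names(events) <- vapply(events, `[[`, "", "id")
  doc <- structure(
    list(doc_id = doc_id, text = text, sentences = sentences,
         entities = entities, events = events),
    class = "standoff_document"
  )
  check_event_references(doc)
  doc
}

empty_entities <- function() {
  tibble(id = character(), type = character(), char_start = integer(),
         char_end = integer(), sentence = character(), head_token = integer(),
         tokens = list())
}

check_event_references <- function(doc) {
  known <- c(doc$entities$id, names(doc$events))
  for (ev in doc$events) {
    bad <- setdiff(ev$args$target, known)
    if (length(bad)) {
      abort(paste0("event ", ev$id, " references unknown id: ",
                   paste(bad, collapse = ", ")))
    }
  }
  # argument reference graph must be acyclic
  marks <- new.env(parent = emptyenv())
  visit <- function(id, stack) {
    if (id %in% stack) abort(paste0("cyclic event argument references at ", id))
    ev <- doc$events[[id]]
    for (tg in ev$args$target) {
      if (startsWith(tg, "E")) visit(tg, c(stack, id))
    }
  }
  for (id in names(doc$events)) visit(id, character())
  invisible(doc)
}

#' @export
print.standoff_document <- function(x, ...) {
  cat("<standoff_document ", x$doc_id, ": ", length(x$sentences),
      " sentence(s), ", nrow(x$entities), " entities, ", length(x$events),
      " events>\n", sep = "")
  invisible(x)
}

read_lines_arg <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  if (length(x) == 1 && grepl("\n", x)) return(strsplit(x, "\n")[[1]])
  as.character(x)
}

#' Read one dependency parse block into a sentence graph
#'
#' Two dialects are accepted and may be mixed within a block:
#' \itemize{
#'   \item CoNLL-style rows with tab/space separated columns
#'     `index surface lemma pos governor label`; `governor` 0 (or `_`)
#'     declares a root token with no incoming edge from this row.
#'   \item textual edge lines `label(surface-i/POS, surface-j/POS)`, the
#'     governor first, mirroring the usual collapsed-dependency rendering.
#'     Bare `surface-i/POS` lines declare edge-less tokens.
#' }
#' A purely textual block has no lemma column; lemmas then default to the
#' lowercased surface form, so the two dialects parse to identical graphs
#' whenever lemmas are lowercase surfaces.
#'
#' @param rows character vector of lines (or a file path) for one sentence.
#' @param sentence_id identifier for the resulting graph.
#' @return a [sentence_graph()].
#' @export
read_dependency_graph <- function(rows, sentence_id = "s1") {
  lines <- read_lines_arg(rows, "parse")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  tok <- list(); edg <- list(governor = integer(), dependent = integer(),
                             label = character())
  declare <- function(idx, surface, pos, lemma = tolower(surface)) {
    key <- as.character(idx)
    prev <- tok[[key]]
    if (!is.null(prev)) {
      if (prev$surface != surface || prev$pos != pos) {
        abort(paste0("conflicting declarations for token ", idx))
      }
      return(invisible(NULL))
    }
    tok[[key]] <<- list(index = idx, surface = surface, lemma = lemma, pos = pos)
    invisible(NULL)
  }
  parse_ref <- function(ref) {
    m <- regmatches(ref, regexec("^(.*)-([0-9]+)/([^/]+)$", ref))[[1]]
    if (length(m) != 4) abort(paste0("malformed token reference: ", ref))
    list(surface = m[2], index = as.integer(m[3]), pos = m[4])
  }
  edge_re <- "^([^()[:space:]]+)\\(([^,]+),[[:space:]]*([^)]+)\\)$"
  for (ln in lines) {
    if (grepl(edge_re, ln)) {
      m <- regmatches(ln, regexec(edge_re, ln))[[1]]
      gv <- parse_ref(m[3]); dp <- parse_ref(m[4])
      declare(gv$index, gv$surface, gv$pos)
      declare(dp$index, dp$surface, dp$pos)
      if (any(edg$governor == gv$index & edg$dependent == dp$index &
              edg$label == m[2])) {
        abort(paste0("duplicate edge: ", ln))
      }
      edg$governor <- c(edg$governor, gv$index)
      edg$dependent <- c(edg$dependent, dp$index)
      edg$label <- c(edg$label, m[2])
    } else if (grepl("^[^()[:space:]]+-[0-9]+/[^/]+$", ln)) {
      r <- parse_ref(ln)
      declare(r$index, r$surface, r$pos)
    } else {
      f <- strsplit(ln, "[\t ]+")[[1]]
      if (length(f) < 6) abort(paste0("malformed parse row: ", ln))
      idx <- suppressWarnings(as.integer(f[1]))
      gov <- suppressWarnings(if (f[5] == "_") 0L else as.integer(f[5]))
      if (is.na(idx) || is.na(gov)) abort(paste0("malformed parse row: ", ln))
      declare(idx, f[2], f[4], lemma = f[3])
      if (gov > 0L) {
        if (any(edg$governor == gov & edg$dependent == idx & edg$label == f[6])) {
          abort(paste0("duplicate edge: ", ln))
        }
        edg$governor <- c(edg$governor, gov)
        edg$dependent <- c(edg$dependent, idx)
        edg$label <- c(edg$label, f[6])
      }
    }
  }
  if (!length(tok)) abort("empty parse block")
  bad <- setdiff(c(edg$governor, edg$dependent), map_int(tok, "index"))
  if (length(bad)) abort(paste0("edge references undeclared token ", bad[1]))
  ord <- order(map_int(tok, "index"))
  tokens <- token_table(
    index = map_int(tok, "index")[ord],
    surface = map_chr(tok, "surface")[ord],
    lemma = map_chr(tok, "lemma")[ord],
    pos = map_chr(tok, "pos")[ord]
  )
  sentence_graph(tokens, do.call(edge_table, edg), sentence_id)
}

split_blocks <- function(lines) {
  lines <- sub("\r$", "", lines)
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(blank & !c(TRUE, blank[-length(blank)]))
  grp[blank] <- NA
  out <- split(lines[!blank], grp[!blank])
  unname(out)
}

# locate each token's character span inside its sentence, scanning left to
# right; parse token order must follow surface order in the text.
token_spans <- function(sentence_text, surfaces, sent_start) {
  cursor <- 1L
  starts <- integer(length(surfaces)); ends <- integer(length(surfaces))
  for (i in seq_along(surfaces)) {
    hit <- regexpr(surfaces[i], substring(sentence_text, cursor), fixed = TRUE)
    if (hit < 0) {
      abort(paste0("token '", surfaces[i], "' not found in sentence text ",
                   "(parse/tokenization mismatch)"))
    }
    starts[i] <- cursor + hit - 1L
    ends[i] <- starts[i] + attr(hit, "match.length")
    cursor <- ends[i]
  }
  tibble(char_start = sent_start + starts - 1L, char_end = sent_start + ends - 1L)
}

parse_a1 <- function(lines) {
  out <- tibble(id = character(), type = character(), char_start = integer(),
                char_end = integer(), text = character())
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1]]
    if (length(f) < 2 || !grepl("^T[0-9]+$", f[1])) {
      abort(paste0("malformed a1 line: ", ln))
    }
    g <- strsplit(f[2], " ")[[1]]
    out <- bind_rows(out, tibble(
      id = f[1], type = g[1],
      char_start = as.integer(g[2]), char_end = as.integer(g[3]),
      text = if (length(f) >= 3) f[3] else NA_character_))
  }
  out
}

#' Read a standoff-annotated document
#'
#' Reads BioNLP shared-task style standoff input: the raw text (one sentence
#' per line), `.a1` entity annotations, optional `.a2` trigger/event
#' annotations, and one dependency-parse block per sentence (blocks separated
#' by blank lines, see [read_dependency_graph()]). Character offsets are
#' 0-based half-open; token indices are 1-based and sentence-local. Events
#' whose trigger or arguments span more than one sentence are dropped with a
#' warning. When `a2` is absent the document carries entities only (test
#' mode).
#'
#' @param txt document text (string with newlines, or path).
#' @param a1 entity annotation lines (vector or path).
#' @param a2 event annotation lines (vector or path), or `NULL`.
#' @param parses dependency parse lines (vector or path).
#' @param doc_id document identifier.
#' @return a [standoff_document()].
#' @export
read_standoff_document <- function(txt, a1, a2 = NULL, parses, doc_id = "doc") {
  text <- paste(read_lines_arg(txt, "txt"), collapse = "\n")
  sent_text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  sent_start <- c(1L, head(cumsum(nchar(sent_text) + 1L), -1) + 1L)
  blocks <- split_blocks(read_lines_arg(parses, "parses"))
  if (length(blocks) != length(sent_text)) {
    abort(paste0("parse blocks (", length(blocks), ") do not match sentences (",
                 length(sent_text), ")"))
  }
  sentences <- vector("list", length(blocks))
  spans <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    sid <- paste0("s", i)
    g <- read_dependency_graph(blocks[[i]], sentence_id = sid)
    sp <- token_spans(sent_text[i], g$tokens$surface, sent_start[i])
    spans[[i]] <- sp
    sentences[[i]] <- g
  }

  locate_span <- function(id, cs, ce) {
    if (cs < 0 || ce > nchar(text) || cs >= ce) {
      abort(paste0("annotation ", id, " offsets out of range"))
    }
    si <- findInterval(cs + 1L, sent_start)
    sp <- spans[[si]]
    hit <- which(sp$char_start - 1L < ce & sp$char_end - 1L > cs)
    if (!length(hit)) abort(paste0("annotation ", id, " covers no token"))
    list(sentence = si, tokens = sentences[[si]]$tokens$index[hit])
  }
  head_of <- function(si, toks) {
    if (length(toks) == 1) return(toks)
    g <- sentences[[si]]
    has_internal_gov <- vapply(toks, function(t) {
      gv <- g$edges$governor[g$edges$dependent == t]
      any(gv %in% toks)
    }, logical(1))
    cand <- toks[!has_internal_gov]
    if (!length(cand)) cand <- toks
    max(cand)  # ties broken by rightmost
  }

  a1_tab <- parse_a1(read_lines_arg(a1, "a1"))
  entities <- empty_entities()
  for (k in seq_len(nrow(a1_tab))) {
    loc <- locate_span(a1_tab$id[k], a1_tab$char_start[k], a1_tab$char_end[k])
    entities <- bind_rows(entities, tibble(
      id = a1_tab$id[k], type = a1_tab$type[k],
      char_start = a1_tab$char_start[k], char_end = a1_tab$char_end[k],
      sentence = paste0("s", loc$sentence),
      head_token = head_of(loc$sentence, loc$tokens),
      tokens = list(loc$tokens)))
  }

  events <- list()
  a2_lines <- read_lines_arg(a2, "a2")
  if (!is.null(a2_lines) && length(a2_lines)) {
    a2_lines <- a2_lines[nzchar(trimws(a2_lines))]
    trig <- parse_a1(a2_lines[grepl("^T", a2_lines)])
    ev_lines <- a2_lines[grepl("^E", a2_lines)]
    trig_loc <- list()
    for (k in seq_len(nrow(trig))) {
      trig_loc[[trig$id[k]]] <- locate_span(trig$id[k], trig$char_start[k],
                                            trig$char_end[k])
    }
    for (ln in ev_lines) {
      f <- strsplit(ln, "\t")[[1]]
      parts <- strsplit(f[2], " ")[[1]]
      ty <- strsplit(parts[1], ":")[[1]]
      tl <- trig_loc[[ty[2]]]
      if (is.null(tl)) abort(paste0("event ", f[1], " has unknown trigger ", ty[2]))
      args <- tibble(role = character(), target = character())
      for (p in parts[-1]) {
        rt <- strsplit(p, ":")[[1]]
        args <- bind_rows(args, tibble(role = rt[1], target = rt[2]))
      }
      events[[f[1]]] <- list(
        id = f[1], type = ty[1], trigger_id = ty[2],
        sentence = paste0("s", tl$sentence),
        trigger_tokens = tl$tokens,
        trigger_span = c(trig$char_start[trig$id == ty[2]],
                         trig$char_end[trig$id == ty[2]]),
        args = args)
    }
    # resolve targets: entity ids must exist; event ids must exist
    known <- c(entities$id, names(events))
    for (ev in events) {
      bad <- setdiff(ev$args$target, known)
      if (length(bad)) {
        abort(paste0("event ", ev$id, " has dangling argument: ",
                     paste(bad, collapse = ", ")))
      }
    }
    events <- drop_cross_sentence_events(events, entities)
  }
  standoff_document(doc_id, text, sentences, entities, events)
}

# single-sentence scope: drop events not fully contained in one sentence,
# including events that (transitively) reference a dropped event.
drop_cross_sentence_events <- function(events, entities) {
  ent_sent <- setNames(entities$sentence, entities$id)
  keep <- setNames(rep(NA, length(events)), names(events))
  sent_of <- function(id) {
    if (startsWith(id, "T")) return(ent_sent[[id]])
    events[[id]]$sentence
  }
  ok <- function(id) {
    if (!is.na(keep[[id]])) return(keep[[id]])
    ev <- events[[id]]
    good <- all(vapply(ev$args$target, function(tg) {
      s <- sent_of(tg)
      if (startsWith(tg, "E") && !ok(tg)) return(FALSE)
      identical(s, ev$sentence)
    }, logical(1)))
    keep[[id]] <<- good
    good
  }
  for (id in names(events)) ok(id)
  dropped <- names(events)[!unlist(keep[names(events)])]
  if (length(dropped)) {
    warn(paste0("dropping cross-sentence event(s): ",
                paste(dropped, collapse = ", ")))
  }
  events[setdiff(names(events), dropped)]
}

#' Anonymize entity mentions for pattern generalization
#'
#' Replaces each entity's head token content (surface and lemma) with a
#' generic string representing the entity type (e.g. `"Protein"`), or with
#' the single string `"BIO_Entity"` when `generic = "bio_entity"`, so that
#' induced patterns abstract away the specific entity. Non-head tokens inside
#' a multi-token entity span are flagged as absorbed and excluded from path
#' endpoints. Token counts and edge sets are never changed.
#'
#' @param doc a [standoff_document()] with resolved entity head tokens.
#' @param generic `"per_type"` (default) or `"bio_entity"`.
#' @return the anonymized document.
#' @export
anonymize_entities <- function(doc, generic = c("per_type", "bio_entity")) {
  generic <- match.arg(generic)
  if (anyDuplicated(doc$entities[, c("sentence", "head_token")])) {
    abort("two entities share a head token")
  }
  if (is.null(doc$orig_surfaces)) {
    doc$orig_surfaces <- lapply(doc$sentences, function(g) g$tokens$surface)
    names(doc$orig_surfaces) <- names(doc$sentences)
  }
  for (k in seq_len(nrow(doc$entities))) {
    e <- doc$entities[k, ]
    gstr <- if (generic == "bio_entity") "BIO_Entity" else e$type
    g <- doc$sentences[[e$sentence]]
    i <- match(e$head_token, g$tokens$index)
    g$tokens$surface[i] <- gstr
    g$tokens$lemma[i] <- gstr
    g$tokens$entity_type[i] <- gstr
    g$tokens$is_entity[i] <- TRUE
    others <- setdiff(e$tokens[[1]], e$head_token)
    g$tokens$absorbed[g$tokens$index %in% others] <- TRUE
    doc$sentences[[e$sentence]] <- g
  }
  doc$anonymized <- TRUE
  doc
}

#' Serialize a document's events as a2 annotation lines
#'
#' Emits trigger `T` lines followed by event `E` lines; reading the output
#' back with [read_standoff_document()] reproduces the same events.
#'
#' @param doc a [standoff_document()].
#' @return character vector of a2 lines (empty for a document with no events).
#' @export
write_a2 <- function(doc) {
  check_event_references(doc)
  if (!length(doc$events)) return(character())
  spans <- doc_token_spans(doc)
  # stable trigger numbering continuing after the a1 T ids
  t_next <- max(c(0L, as.integer(sub("^T", "", doc$entities$id)))) + 1L
  trig_ids <- character(); trig_lines <- character()
  t_key <- function(ev) paste(ev$sentence, paste(ev$trigger_tokens, collapse = ","))
  lines <- character()
  for (ev in doc$events) {
    key <- t_key(ev)
    if (!key %in% names(trig_ids)) {
      sp <- spans[[ev$sentence]]
      ii <- match(ev$trigger_tokens, doc$sentences[[ev$sentence]]$tokens$index)
      cs <- min(sp$char_start[ii]) - 1L; ce <- max(sp$char_end[ii]) - 1L
      txt <- substring(doc$text, cs + 1L, ce)
      id <- paste0("T", t_next); t_next <- t_next + 1L
      trig_ids[key] <- id
      trig_lines <- c(trig_lines,
                      paste0(id, "\t", ev$type, " ", cs, " ", ce, "\t", txt))
    }
    arg_str <- if (nrow(ev$args)) {
      paste(paste0(ev$args$role, ":", ev$args$target), collapse = " ")
    } else ""
    body <- paste0(ev$type, ":", trig_ids[key],
                   if (nzchar(arg_str)) paste0(" ", arg_str) else "")
    lines <- c(lines, paste0(ev$id, "\t", body))
  }
  c(trig_lines, lines)
}

doc_token_spans <- function(doc) {
  sent_text <- strsplit(doc$text, "\n", fixed = TRUE)[[1]]
  sent_start <- c(1L, head(cumsum(nchar(sent_text) + 1L), -1) + 1L)
  out <- list()
  for (i in seq_along(doc$sentences)) {
    g <- doc$sentences[[i]]
    surf <- g$tokens$surface
    # anonymized tokens no longer appear in the text; fall back to original
    if (!is.null(doc$orig_surfaces) &&
        !is.null(doc$orig_surfaces[[g$sentence_id]])) {
      surf <- doc$orig_surfaces[[g$sentence_id]]
    }
    out[[g$sentence_id]] <- token_spans(sent_text[i], surf, sent_start[i])
  }
  out
}

#' Serialize a document to standoff files
#'
#' Writes (or returns) the `.txt`, `.a1`, `.a2` and dependency-parse streams
#' for a document. The parse stream uses the CoNLL-style table for
#' single-governor tokens plus textual edge lines for any additional edges,
#' which [read_standoff_document()] reads back losslessly.
#'
#' @param doc a [standoff_document()] (not yet anonymized).
#' @param dir output directory, or `NULL` to return the streams.
#' @return invisibly, a list with elements `txt`, `a1`, `a2`, `parse`.
#' @export
write_standoff_document <- function(doc, dir = NULL) {
  a1 <- vapply(seq_len(nrow(doc$entities)), function(k) {
    e <- doc$entities[k, ]
    paste0(e$id, "\t", e$type, " ", e$char_start, " ", e$char_end, "\t",
           substring(doc$text, e$char_start + 1L, e$char_end))
  }, character(1))
  parse_blocks <- vapply(doc$sentences, function(g) {
    seen <- logical(nrow(g$edges))
    rows <- vapply(seq_len(nrow(g$tokens)), function(i) {
      t <- g$tokens[i, ]
      k <- which(!seen & g$edges$dependent == t$index)
      if (length(k)) {
        k <- k[1]; seen[k] <<- TRUE
        paste(t$index, t$surface, t$lemma, t$pos, g$edges$governor[k],
              g$edges$label[k], sep = "\t")
      } else {
        paste(t$index, t$surface, t$lemma, t$pos, 0L, "dep", sep = "\t")
      }
    }, character(1))
    extra <- if (any(!seen)) format_edges(g, g$edges[!seen, ]) else character()
    paste(c(rows, extra), collapse = "\n")
  }, character(1))
  out <- list(
    txt = strsplit(doc$text, "\n", fixed = TRUE)[[1]],
    a1 = a1,
    a2 = write_a2(doc),
    parse = paste(parse_blocks, collapse = "\n\n")
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(out$txt, file.path(dir, paste0(doc$doc_id, ".txt")))
    writeLines(out$a1, file.path(dir, paste0(doc$doc_id, ".a1")))
    writeLines(out$a2, file.path(dir, paste0(doc$doc_id, ".a2")))
    writeLines(out$parse, file.path(dir, paste0(doc$doc_id, ".parse")))
  }
  invisible(out)
}

#' Read a directory of standoff documents
#'
#' Expects `<id>.txt`, `<id>.a1`, optional `<id>.a2` and `<id>.parse` files.
#'
#' @param dir directory path.
#' @return list of [standoff_document()].
#' @export
read_standoff_dir <- function(dir) {
  ids <- sub("\\.txt$", "", basename(list.files(dir, pattern = "\\.txt$")))
  lapply(ids, function(id) {
    a2 <- file.path(dir, paste0(id, ".a2"))
    read_standoff_document(
      txt = file.path(dir, paste0(id, ".txt")),
      a1 = file.path(dir, paste0(id, ".a1")),
      a2 = if (file.exists(a2)) a2 else NULL,
      parses = file.path(dir, paste0(id, ".parse")),
      doc_id = id)
  })
}
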