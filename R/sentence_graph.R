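#' Collapse a Penn Treebank tag to its relaxed base class
#'
#' Relaxed POS tags ("P*") let a plural noun match a singular form and the
#' various conjugated forms of a verb match each other: every `NN*` tag maps
#' to `"NN"` and every `VB*` tag to `"VB"`; all other tags map to themselves.
#' The function is idempotent.
#'
#' @param pos character vector of Penn Treebank POS tags.
#' @return character vector of the same length with collapsed tags.
#' @examples
#' relaxed_pos(c("NNS", "VBD", "JJ"))
#' @export
relaxed_pos <- function(pos) {
  stopifnot(is.character(pos))
  if (any(!nzchar(pos) | is.na(pos))) {
    abort("POS tags must be non-empty strings.")
  }
  out <- pos
  out[startsWith(out, "NN")] <- "NN"
  out[startsWith(out, "VB")] <- "VB"
  out
}

#' Build a token table
#'
#' Tokens are the nodes of a [sentence_graph()]. Indices are 1-based and must
#' be unique; `relaxed_pos` is always derived from `pos`, and the entity flag
#' is kept consistent with `entity_type` (a token is an entity token iff its
#' generic type string is non-empty).
#'
#' @param index integer vector of 1-based token positions.
#' @param surface,lemma,pos character vectors (recycled to length of `index`).
#' @param entity_type generic entity type string, `""` for ordinary tokens.
#' @param absorbed logical; `TRUE` for non-head tokens inside a multi-token
#'   entity span, which are excluded from path endpoints and match images.
#' @return a tibble with class-invariant token columns.
#' @export
token_table <- function(index, surface, lemma = tolower(surface), pos = "NN",
                        entity_type = "", absorbed = FALSE) {
  n <- length(index)
  tok <- tibble(
    index = as.integer(index),
    surface = rep_len(as.character(surface), n),
    lemma = rep_len(as.character(lemma), n),
    pos = rep_len(as.character(pos), n),
    entity_type = rep_len(as.character(entity_type), n),
    absorbed = rep_len(as.logical(absorbed), n)
  )
  if (any(tok$index < 1L)) abort("token indices must be >= 1")
  if (anyDuplicated(tok$index)) abort("duplicate token indices")
  tok$relaxed_pos <- relaxed_pos(tok$pos)
  tok$is_entity <- nzchar(tok$entity_type)
  tok[order(tok$index), c("index", "surface", "lemma", "pos", "relaxed_pos",
                          "is_entity", "entity_type", "absorbed")]
}

#' Build an edge table of labeled directed dependencies
#'
#' @param governor,dependent integer token indices.
#' @param label dependency relation strings (e.g. `"nsubj"`, `"prep_to"`).
#' @return tibble with columns governor, dependent, label.
#' @export
edge_table <- function(governor = integer(), dependent = integer(),
                       label = character()) {
  e <- tibble(
    governor = as.integer(governor),
    dependent = as.integer(dependent),
    label = as.character(label)
  )
  if (any(e$governor == e$dependent)) abort("self-loop dependency edge")
  if (anyDuplicated(e[, c("governor", "dependent", "label")])) {
    abort("duplicate (governor, dependent, label) triple")
  }
  e
}

#' Construct a sentence dependency graph
#'
#' A sentence graph G_s = (V_s, E_s) holds the tokens of one sentence as
#' nodes and its labeled, directed dependency relations as edges. The graph
#' may be disconnected; every edge must reference declared tokens.
#'
#' @param tokens a [token_table()].
#' @param edges an [edge_table()].
#' @param sentence_id identifier string.
#' @return an object of class `sentence_graph`.
#' @export
sentence_graph <- function(tokens, edges = edge_table(), sentence_id = "s1") {
  if (!all(c("index", "lemma", "pos") %in% names(tokens))) {
    tokens <- do.call(token_table, as.list(tokens))
  }
  edges <- edge_table(edges$governor, edges$dependent, edges$label)
  bad <- setdiff(c(edges$governor, edges$dependent), tokens$index)
  if (length(bad)) {
    abort(paste0("edge references unknown token index: ",
                 paste(bad, collapse = ", ")))
  }
  structure(
    list(sentence_id = as.character(sentence_id), tokens = tokens,
         edges = edges),
    class = "sentence_graph"
  )
}

#' @export
print.sentence_graph <- function(x, ...) {
  cat("<sentence_graph ", x$sentence_id, ": ", nrow(x$tokens), " tokens, ",
      nrow(x$edges), " edges>\n", sep = "")
  if (nrow(x$edges)) {
    cat(paste0(" ", format_edges(x), collapse = "\n"), "\n", sep = "")
  }
  invisible(x)
}

# "label(gov-i/POS, dep-j/POS)" rendering used by printing, the pattern
# store, and the textual parse dialect.
format_edges <- function(g, edges = g$edges) {
  tok <- g$tokens
  ref <- function(i) {
    k <- match(i, tok$index)
    paste0(tok$surface[k], "-", i, "/", tok$pos[k])
  }
  sprintf("%s(%s, %s)", edges$label, ref(edges$governor), ref(edges$dependent))
}

# undirected adjacency list: for each token index, tibble of (other, label,
# out) rows where out=TRUE means the edge is governor=self -> dependent=other.
adjacency_list <- function(g) {
  idx <- g$tokens$index
  adj <- setNames(vector("list", length(idx)), as.character(idx))
  for (i in seq_along(idx)) adj[[i]] <- list(other = integer(), label = character(), out = logical())
  for (k in seq_len(nrow(g$edges))) {
    gv <- as.character(g$edges$governor[k]); dp <- as.character(g$edges$dependent[k])
    adj[[gv]]$other <- c(adj[[gv]]$other, g$edges$dependent[k])
    adj[[gv]]$label <- c(adj[[gv]]$label, g$edges$label[k])
    adj[[gv]]$out <- c(adj[[gv]]$out, TRUE)
    adj[[dp]]$other <- c(adj[[dp]]$other, g$edges$governor[k])
    adj[[dp]]$label <- c(adj[[dp]]$label, g$edges$label[k])
    adj[[dp]]$out <- c(adj[[dp]]$out, FALSE)
  }
  adj
}

as_igraph_undirected <- function(g) {
  verts <- data.frame(name = as.character(g$tokens$index))
  if (nrow(g$edges) == 0) {
    return(igraph::graph_from_data_frame(
      data.frame(from = character(), to = character()),
      directed = FALSE, vertices = verts))
  }
  igraph::graph_from_data_frame(
    data.frame(from = as.character(g$edges$governor),
               to = as.character(g$edges$dependent)),
    directed = FALSE, vertices = verts)
}
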