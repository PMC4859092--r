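#' Construct a signed directed pathway graph
#'
#' A `PathwayGraph` is the package's representation of one KEGG-style pathway:
#' nodes are gene sets (or compounds, or flattened KGML groups), edges are
#' signed interactions (+1 activation, -1 inhibition), and sources/sinks are
#' the nodes with zero in-/out-degree. Sinks are where pathway signal flow
#' (PSF) values are read out.
#'
#' @param pathway_id Character scalar identifier (e.g. `"hsa04662"`).
#' @param name Human-readable pathway name.
#' @param nodes Data frame with columns `node_id`, `node_kind`
#'   (`"gene"`, `"compound"` or `"group"`), `label`, and a list column
#'   `gene_ids` (character vectors; may be empty for compounds).
#' @param edges Data frame with columns `from`, `to`, `sign` (+1 or -1) and
#'   `subtype` (free-text KGML relation subtype).
#' @return An object of class `PathwayGraph`.
#' @export
pathway_graph <- function(pathway_id, name = pathway_id, nodes, edges) {
  stopifnot(is.character(pathway_id), length(pathway_id) == 1L)
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        sign = integer(), subtype = character(),
                        stringsAsFactors = FALSE)
  }
  if (anyDuplicated(nodes$node_id)) {
    stop("duplicate node_id in pathway '", pathway_id, "'")
  }
  edges$sign <- as.integer(edges$sign)
  if (!all(edges$sign %in% c(1L, -1L))) {
    stop("edge sign must be +1 or -1 in pathway '", pathway_id, "'")
  }
  missing_ep <- setdiff(unique(c(edges$from, edges$to)), nodes$node_id)
  if (length(missing_ep)) {
    stop("edge endpoint(s) not in node set of '", pathway_id, "': ",
         paste(missing_ep, collapse = ", "))
  }
  bad <- nodes$node_kind == "gene" & lengths(nodes$gene_ids) == 0L
  if (any(bad)) {
    stop("gene node(s) with empty gene_ids in '", pathway_id, "': ",
         paste(nodes$node_id[bad], collapse = ", "))
  }
  # drop exact duplicate edges (set semantics)
  edges <- edges[!duplicated(edges[, c("from", "to", "sign", "subtype")]), ,
                 drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  g <- structure(
    list(pathway_id = pathway_id, name = name, nodes = nodes, edges = edges,
         removed_edges = edges[0, , drop = FALSE]),
    class = "PathwayGraph"
  )
  g$sources <- graph_sources(g)
  g$sinks <- graph_sinks(g)
  g
}

graph_sources <- function(g) {
  sort(setdiff(g$nodes$node_id, g$edges$to))
}

graph_sinks <- function(g) {
  sort(setdiff(g$nodes$node_id, g$edges$from))
}

#' @export
print.PathwayGraph <- function(x, ...) {
  cat(sprintf("PathwayGraph '%s' (%s)\n", x$pathway_id, x$name))
  cat(sprintf("  %d nodes, %d edges (%d inhibitory)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$sign == -1L)))
  cat(sprintf("  sources: %s\n", paste(x$sources, collapse = ", ")))
  cat(sprintf("  sinks:   %s\n", paste(x$sinks, collapse = ", ")))
  invisible(x)
}

# Kahn topological order; returns node ids or NULL if the graph is cyclic.
topological_order <- function(g) {
  ids <- sort(g$nodes$node_id)
  indeg <- setNames(integer(length(ids)), ids)
  tab <- table(g$edges$to)
  indeg[names(tab)] <- as.integer(tab)
  out_adj <- split(g$edges$to, factor(g$edges$from, levels = ids))
  order <- character(0)
  queue <- ids[indeg == 0L]
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    for (w in out_adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- sort(c(queue, w))
    }
  }
  if (length(order) < length(ids)) NULL else order
}

is_acyclic <- function(g) !is.null(topological_order(g))

#' Serialize a pathway graph to JSON
#'
#' Writes nodes, signed edges, sources and sinks as a JSON document that
#' [pathway_from_json()] reads back losslessly.
#'
#' @param g A `PathwayGraph`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to `path`).
#' @export
pathway_to_json <- function(g, path = NULL) {
  obj <- list(
    pathway_id = g$pathway_id,
    name = g$name,
    nodes = lapply(seq_len(nrow(g$nodes)), function(i) list(
      node_id = g$nodes$node_id[i],
      node_kind = g$nodes$node_kind[i],
      label = g$nodes$label[i],
      gene_ids = as.list(g$nodes$gene_ids[[i]])
    )),
    edges = lapply(seq_len(nrow(g$edges)), function(i) list(
      from = g$edges$from[i], to = g$edges$to[i],
      sign = g$edges$sign[i], subtype = g$edges$subtype[i]
    )),
    sources = as.list(g$sources),
    sinks = as.list(g$sinks)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a pathway graph from its JSON serialization
#'
#' @param x JSON string or file path produced by [pathway_to_json()].
#' @return A `PathwayGraph`.
#' @export
pathway_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  nodes <- data.frame(
    node_id = vapply(obj$nodes, `[[`, "", "node_id"),
    node_kind = vapply(obj$nodes, `[[`, "", "node_kind"),
    label = vapply(obj$nodes, `[[`, "", "label"),
    stringsAsFactors = FALSE
  )
  nodes$gene_ids <- lapply(obj$nodes, function(n) unlist(n$gene_ids) %||% character(0))
  edges <- data.frame(
    from = vapply(obj$edges, `[[`, "", "from"),
    to = vapply(obj$edges, `[[`, "", "to"),
    sign = vapply(obj$edges, function(e) as.integer(e$sign), 0L),
    subtype = vapply(obj$edges, `[[`, "", "subtype"),
    stringsAsFactors = FALSE
  )
  pathway_graph(obj$pathway_id, obj$name, nodes, edges)
}
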