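#' Remove feedback edges so a pathway graph becomes acyclic
#'
#' KEGG maps contain feedback loops, but signal propagation needs a
#' topological order. This routine performs a depth-first search starting
#' from the in-degree-zero nodes (in lexicographic `node_id` order, so the
#' result is deterministic) and deletes every back edge it meets — an edge
#' pointing at a node currently on the DFS stack. Nodes unreachable from any
#' source are then searched the same way so that no cycle survives. Removed
#' edges are recorded in the `removed_edges` field and reported via a
#' message.
#'
#' @param g A `PathwayGraph`.
#' @return An acyclic `PathwayGraph`; sources/sinks are recomputed.
#' @export
break_cycles <- function(g) {
  ids <- sort(g$nodes$node_id)
  roots <- graph_sources(g)
  if (length(roots) == 0L) {
    stop("no sources after cycle analysis in pathway '", g$pathway_id,
         "': every node lies on a cycle")
  }
  edges <- g$edges
  # adjacency as edge-row indices, children visited in sorted node order
  adj <- lapply(setNames(ids, ids), function(v) {
    idx <- which(edges$from == v)
    idx[order(edges$to[idx])]
  })
  state <- setNames(rep.int(0L, length(ids)), ids) # 0 new, 1 on stack, 2 done
  drop_idx <- integer(0)

  visit <- function(root) {
    # iterative DFS (explicit stack) to avoid deep recursion on long chains
    state[root] <<- 1L
    node_stack <- root
    child_stack <- 1L
    while (length(node_stack)) {
      d <- length(node_stack)
      v <- node_stack[d]
      kids <- adj[[v]]
      ci <- child_stack[d]
      if (ci > length(kids)) {
        state[v] <<- 2L
        node_stack <- node_stack[-d]
        child_stack <- child_stack[-d]
        next
      }
      child_stack[d] <- ci + 1L
      ei <- kids[ci]
      w <- edges$to[ei]
      if (state[w] == 1L) {
        drop_idx <<- c(drop_idx, ei)        # back edge: breaks a cycle
      } else if (state[w] == 0L) {
        state[w] <<- 1L
        node_stack <- c(node_stack, w)
        child_stack <- c(child_stack, 1L)
      }
    }
  }

  for (r in roots) if (state[r] == 0L) visit(r)
  for (r in ids) if (state[r] == 0L) visit(r)  # components unreachable from sources

  removed <- edges[drop_idx, , drop = FALSE]
  kept <- if (length(drop_idx)) edges[-drop_idx, , drop = FALSE] else edges
  out <- pathway_graph(g$pathway_id, g$name, g$nodes, kept)
  out$removed_edges <- removed
  if (nrow(removed)) {
    psf_log(sprintf("break_cycles('%s'): removed %d back edge(s): %s",
                    g$pathway_id, nrow(removed),
                    paste(removed$from, "->", removed$to, collapse = ", ")))
  }
  if (!is_acyclic(out)) {
    stop("internal error: graph still cyclic after back-edge removal")
  }
  out
}

#' Filter a pathway collection
#'
#' Drops pathways whose id appears in a user-supplied exclusion list (e.g.
#' disease- and drug-response-specific maps) and pathways without any
#' annotated interaction (zero edges).
#'
#' @param graphs List of `PathwayGraph` objects.
#' @param exclusion_ids Character vector of pathway ids to exclude, e.g. read
#'   with [read_exclusion_file()].
#' @return Filtered list of `PathwayGraph` objects (possibly empty, with a
#'   warning).
#' @export
filter_pathway_collection <- function(graphs, exclusion_ids = character(0)) {
  keep <- vapply(graphs, function(g) {
    !(g$pathway_id %in% exclusion_ids) && nrow(g$edges) > 0L
  }, logical(1))
  out <- graphs[keep]
  if (length(out) == 0L) warning("no pathways retained after filtering")
  out
}

#' Read a pathway exclusion list
#'
#' One pathway id per line; blank lines and lines starting with `#` are
#' ignored.
#'
#' @param path File path.
#' @return Character vector of pathway ids.
#' @export
read_exclusion_file <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a directory of KGML files
#'
#' @param dir Directory containing `*.xml` KGML files.
#' @return Named list of `PathwayGraph` objects (names = pathway ids), sorted
#'   by pathway id.
#' @export
read_pathway_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.xml$", full.names = TRUE))
  graphs <- lapply(files, parse_kgml)
  names(graphs) <- vapply(graphs, `[[`, "", "pathway_id")
  graphs[order(names(graphs))]
}
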