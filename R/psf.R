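#' Map fold-change values onto pathway nodes
#'
#' Each gene node receives the arithmetic mean fold change of its measured
#' genes. Nodes without any measured gene — including compound nodes, which
#' carry no expression — receive the neutral value `missing_fc` (default 1),
#' so the pathway topology is preserved and the PSF calibration
#' (all-FC-1 gives PSF 1) holds with incomplete expression coverage.
#'
#' @param graph A `PathwayGraph`.
#' @param fc_column Named numeric vector of positive fold changes (names =
#'   gene ids) for one sample.
#' @param missing_fc Neutral fold change for unmeasured genes (default 1).
#' @return List with `weights` (named numeric vector over node ids) and
#'   `coverage` (fraction of gene nodes with at least one measured gene).
#' @export
map_fc_to_nodes <- function(graph, fc_column, missing_fc = 1) {
  if (any(!is.finite(fc_column)) || any(fc_column <= 0)) {
    stop("fold changes must be positive and finite")
  }
  w <- setNames(rep.int(missing_fc, nrow(graph$nodes)), graph$nodes$node_id)
  measured <- logical(nrow(graph$nodes))
  for (i in seq_len(nrow(graph$nodes))) {
    genes <- intersect(graph$nodes$gene_ids[[i]], names(fc_column))
    if (length(genes)) {
      w[i] <- mean(fc_column[genes])
      measured[i] <- TRUE
    }
  }
  is_gene <- graph$nodes$node_kind %in% c("gene", "group")
  coverage <- if (any(is_gene)) mean(measured[is_gene]) else 0
  list(weights = w, coverage = coverage)
}

#' Propagate signal through one pathway and read PSF at the sinks
#'
#' Pathway signal flow: a unit input signal enters every source node
#' (in-degree 0) and is multiplied by that node's fold change. Walking the
#' graph in topological order, each downstream node receives from parent `u`
#' the contribution `signal(u)` across an activating edge and `1/signal(u)`
#' across an inhibiting edge; the node's own signal is its fold change times
#' the arithmetic mean of the parent contributions (so that in-degree does
#' not break the calibration). The PSF of a sink is its signal. When all
#' fold changes equal 1, every sink PSF equals 1 exactly.
#'
#' @param graph Acyclic `PathwayGraph` (run [break_cycles()] first if
#'   needed).
#' @param weights Named numeric vector of positive node fold changes as
#'   returned by [map_fc_to_nodes()] (the `weights` element), or a
#'   node x sample matrix for several samples at once.
#' @param input_signal Signal applied at the sources (default 1).
#' @return Named numeric vector of PSF values at the sinks (or a
#'   sink x sample matrix when `weights` is a matrix).
#' @export
compute_psf <- function(graph, weights, input_signal = 1) {
  topo <- topological_order(graph)
  if (is.null(topo)) {
    stop("pathway '", graph$pathway_id,
         "' contains a cycle; run break_cycles() first")
  }
  W <- if (is.matrix(weights)) weights else
    matrix(weights, ncol = 1, dimnames = list(names(weights), NULL))
  if (!all(graph$nodes$node_id %in% rownames(W))) {
    stop("weights missing for node(s): ",
         paste(setdiff(graph$nodes$node_id, rownames(W)), collapse = ", "))
  }
  W <- W[graph$nodes$node_id, , drop = FALSE]
  if (any(!is.finite(W)) || any(W <= 0)) {
    stop("node weights must be positive and finite")
  }

  n_s <- ncol(W)
  sig <- matrix(NA_real_, nrow = nrow(W), ncol = n_s,
                dimnames = list(graph$nodes$node_id, colnames(W)))
  in_edges <- split(seq_len(nrow(graph$edges)),
                    factor(graph$edges$to, levels = graph$nodes$node_id))
  for (v in topo) {
    ein <- in_edges[[v]]
    if (length(ein) == 0L) {
      sig[v, ] <- input_signal * W[v, ]
    } else {
      contrib <- matrix(0, nrow = length(ein), ncol = n_s)
      for (k in seq_along(ein)) {
        u <- graph$edges$from[ein[k]]
        contrib[k, ] <- if (graph$edges$sign[ein[k]] == 1L) sig[u, ]
                        else 1 / sig[u, ]
      }
      sig[v, ] <- W[v, ] * colMeans(contrib)
    }
  }
  sinks <- graph$sinks
  out <- sig[sinks, , drop = FALSE]
  if (is.matrix(weights)) out else setNames(out[, 1], sinks)
}

#' Compute the PSF matrix for a pathway collection
#'
#' One row per (pathway, sink) pair — row names `"pathway_id:sink_node_id"` —
#' and one column per sample, in deterministic order (pathway id, then sink
#' node id). A pathway whose propagation fails (e.g. residual cycle) is
#' skipped with a log message rather than aborting the whole collection.
#'
#' @param graphs List of acyclic `PathwayGraph` objects.
#' @param fc Gene x sample matrix of positive fold changes (e.g. the `values`
#'   element of [compute_fold_change()]).
#' @param input_signal Source input signal (default 1).
#' @param missing_fc Neutral fold change for unmeasured genes (default 1).
#' @return Sink x sample numeric matrix with attribute `sink_map`, a data
#'   frame with columns `pathway_id`, `node_id`, `sink_id`.
#' @export
compute_psf_matrix <- function(graphs, fc, input_signal = 1, missing_fc = 1) {
  graphs <- graphs[order(vapply(graphs, `[[`, "", "pathway_id"))]
  rows <- list()
  map <- list()
  for (g in graphs) {
    res <- tryCatch({
      W <- node_weight_matrix(g, fc, missing_fc)
      compute_psf(g, W, input_signal)
    }, error = function(e) {
      psf_log("compute_psf_matrix: skipping pathway '", g$pathway_id,
              "': ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    sink_ids <- paste0(g$pathway_id, ":", rownames(res))
    rownames(res) <- sink_ids
    rows[[g$pathway_id]] <- res
    map[[g$pathway_id]] <- data.frame(pathway_id = g$pathway_id,
                                      node_id = g$sinks, sink_id = sink_ids,
                                      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no pathway produced PSF values")
  out <- do.call(rbind, rows)
  colnames(out) <- colnames(fc)
  attr(out, "sink_map") <- do.call(rbind, c(map, list(make.row.names = FALSE)))
  out
}

# node x sample fold-change weights for one pathway (mean over node genes,
# neutral default for unmeasured nodes)
node_weight_matrix <- function(graph, fc, missing_fc = 1) {
  n_s <- ncol(fc)
  W <- matrix(missing_fc, nrow = nrow(graph$nodes), ncol = n_s,
              dimnames = list(graph$nodes$node_id, colnames(fc)))
  for (i in seq_len(nrow(graph$nodes))) {
    genes <- intersect(graph$nodes$gene_ids[[i]], rownames(fc))
    if (length(genes)) {
      W[i, ] <- colMeans(fc[genes, , drop = FALSE])
    }
  }
  W
}

#' Centralize a PSF matrix for SOM training
#'
#' Takes log2 of the PSF values and subtracts the sink-wise mean over all
#' samples, so the analysis focuses on changes of PSF rather than absolute
#' PSF levels; every row of the result has zero mean.
#'
#' @param psf Positive sink x sample PSF matrix.
#' @return Sink x sample matrix of centralized log2 PSF values.
#' @export
centralize_psf <- function(psf) {
  if (any(psf <= 0)) stop("PSF values must be positive")
  lg <- log2(psf)
  out <- sweep(lg, 1, rowMeans(lg))
  attr(out, "sink_map") <- attr(psf, "sink_map")
  out
}
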