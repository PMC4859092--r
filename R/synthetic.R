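#' Describe a synthetic PSF-SOM study
#'
#' Bundles every knob of the synthetic benchmark: the shape of the layered
#' pathway DAGs, the class structure with planted deregulations, and the
#' noise level. Defaults emulate the study conditions the pipeline is
#' validated under: layered branched pathways averaging seven sinks, a
#' healthy control class plus disease classes carrying a multiplicative
#' deregulation of effect size 2 on one pathway branch, 20 samples per class,
#' and multiplicative log-normal noise of 0.3 on the log2 scale.
#'
#' @param n_pathways Number of pathways to generate (default 10).
#' @param n_layers Layers per pathway DAG (default 4; must be >= 2).
#' @param layer_width Width of the internal layers (default 5).
#' @param sinks_target Target number of sinks (last-layer width varies by
#'   +/-1 around it; default 7).
#' @param inhibition_prob Probability that an edge is inhibitory
#'   (default 0.15).
#' @param genes_per_node Genes per gene node (default 2).
#' @param classes Data frame with columns `class_label`, `target_pathway`
#'   (1-based pathway index; `NA` for the control), `target_sink` (1-based
#'   index into the target pathway's sorted sinks), `direction` (`"up"` or
#'   `"down"`), `effect_size` (linear multiplier; 1 for the control),
#'   `n_samples`, `is_control`, and optionally `branch_mode` — `"path"`
#'   (default) plants the lexicographically first source-to-sink path of the
#'   target sink, giving graded downstream effects, while `"pathway"` plants
#'   every gene of the target pathway, deregulating all of its sinks
#'   uniformly (all root-to-sink paths have equal length in the layered
#'   DAGs). Default: one control class `HC` plus four disease classes
#'   `D1`..`D4` targeting pathways 1-4 upward with effect 2, 20 samples
#'   each.
#' @param noise_sd Standard deviation of the log2-scale multiplicative noise
#'   (default 0.3).
#' @param truth_min_log2 Minimum absolute expected log2 PSF for a sink to
#'   count as ground-truth deregulated (default 0.25). Signal is diluted at
#'   nodes averaging several parents, so sinks far from the planted branch
#'   receive arbitrarily small expected shifts; the floor keeps the truth set
#'   at effects detectable in principle under the design's own noise level
#'   (at 20 samples/class and noise 0.3 the standard error of a log2 fold
#'   difference is about 0.1, putting 80 percent power near 0.27).
#' @param seed Master seed (default 1).
#' @return Object of class `SyntheticDesign` (a validated list).
#' @export
synthetic_design <- function(n_pathways = 10, n_layers = 4, layer_width = 5,
                             sinks_target = 7, inhibition_prob = 0.15,
                             genes_per_node = 2, classes = NULL,
                             noise_sd = 0.3, truth_min_log2 = 0.25,
                             seed = 1) {
  if (n_layers < 2) stop("need at least 2 layers")
  if (is.null(classes)) {
    classes <- data.frame(
      class_label = c("HC", paste0("D", 1:4)),
      target_pathway = c(NA, 1, 2, 3, 4),
      target_sink = c(NA, 1, 1, 1, 1),
      direction = c(NA, "up", "up", "up", "up"),
      effect_size = c(1, 2, 2, 2, 2),
      n_samples = rep(20, 5),
      is_control = c(TRUE, rep(FALSE, 4)),
      stringsAsFactors = FALSE
    )
  }
  classes <- as.data.frame(classes, stringsAsFactors = FALSE)
  if (!"target_sink" %in% colnames(classes)) classes$target_sink <- 1L
  if (!"branch_mode" %in% colnames(classes)) classes$branch_mode <- "path"
  if (!all(classes$branch_mode[!classes$is_control] %in% c("path", "pathway"))) {
    stop("branch_mode must be 'path' or 'pathway'")
  }
  classes$target_sink[is.na(classes$target_sink) & !classes$is_control] <- 1L
  if (any(classes$effect_size <= 0)) stop("effect sizes must be positive")
  if (any(classes$n_samples < 2)) stop("need at least 2 samples per class")
  ctrl <- classes$is_control
  if (sum(ctrl) != 1L || classes$effect_size[ctrl] != 1) {
    stop("exactly one control class with effect size 1 is required")
  }
  bad_target <- !ctrl & (is.na(classes$target_pathway) |
                           classes$target_pathway > n_pathways)
  if (any(bad_target)) stop("disease class with invalid target_pathway")
  structure(list(n_pathways = n_pathways, n_layers = n_layers,
                 layer_width = layer_width, sinks_target = sinks_target,
                 inhibition_prob = inhibition_prob,
                 genes_per_node = genes_per_node, classes = classes,
                 noise_sd = noise_sd, truth_min_log2 = truth_min_log2,
                 seed = seed),
            class = "SyntheticDesign")
}

#' Generate a synthetic pathway collection with ground truth
#'
#' Builds layered branched DAGs (every layer-l node keeps at least one child,
#' every layer-l+1 node at least one parent, so sources are exactly the first
#' layer and sinks the last), draws inhibitory edge signs with the configured
#' probability, serializes each pathway as KGML, and derives the ground truth
#' of every disease class: the planted branch (the lexicographically first
#' source-to-sink path of the class's target sink, excluding the sink
#' itself), its genes, and — by noiseless propagation of the planted fold
#' changes — the set of truly affected sinks with their expected log2 PSF.
#'
#' @param design A [synthetic_design()].
#' @return List with `graphs` (named list of `PathwayGraph`), `kgml` (named
#'   character vector of KGML documents) and `truth` (see Details).
#' @export
generate_pathways <- function(design) {
  stopifnot(inherits(design, "SyntheticDesign"))
  graphs <- list()
  kgml <- character(0)
  gene_counter <- 0L
  for (p in seq_len(design$n_pathways)) {
    pid <- sprintf("syn%03d", p)
    gp <- with_seed(derive_seed(design$seed, p), {
      sizes <- c(sample(2:3, 1),
                 rep(design$layer_width, max(0, design$n_layers - 2)),
                 max(1, design$sinks_target + sample(-1:1, 1)))
      build_layered_pathway(pid, sizes, design$inhibition_prob,
                            design$genes_per_node, gene_counter)
    })
    gene_counter <- gp$gene_counter
    graphs[[pid]] <- gp$graph
    kgml[[pid]] <- write_kgml(gp$graph)
  }
  truth <- derive_ground_truth(design, graphs)
  list(graphs = graphs, kgml = kgml, truth = truth)
}

build_layered_pathway <- function(pid, sizes, inhibition_prob,
                                  genes_per_node, gene_counter) {
  n_nodes <- sum(sizes)
  layer <- rep(seq_along(sizes), sizes)
  node_id <- sprintf("n%02d", seq_len(n_nodes))
  gene_ids <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) {
    gene_ids[[i]] <- sprintf("%s_g%04d", pid, gene_counter + seq_len(genes_per_node))
    gene_counter <- gene_counter + genes_per_node
  }
  nodes <- data.frame(node_id = node_id, node_kind = "gene",
                      label = paste0(toupper(pid), "_", node_id),
                      stringsAsFactors = FALSE)
  nodes$gene_ids <- gene_ids
  from <- character(0); to <- character(0); sgn <- integer(0)
  for (l in seq_len(length(sizes) - 1L)) {
    up <- node_id[layer == l]
    down <- node_id[layer == l + 1L]
    for (d in down) {
      parents <- sample(up, min(length(up), sample(1:2, 1)))
      from <- c(from, parents); to <- c(to, rep(d, length(parents)))
    }
    childless <- setdiff(up, from[to %in% down])
    for (u in childless) {
      from <- c(from, u); to <- c(to, sample(down, 1))
    }
  }
  sgn <- ifelse(runif(length(from)) < inhibition_prob, -1L, 1L)
  edges <- data.frame(from = from, to = to, sign = sgn, subtype = "",
                      stringsAsFactors = FALSE)
  list(graph = pathway_graph(pid, paste("Synthetic pathway", pid),
                             nodes, edges),
       gene_counter = gene_counter)
}

derive_ground_truth <- function(design, graphs) {
  cls <- design$classes
  class_truth <- list()
  for (i in seq_len(nrow(cls))) {
    if (cls$is_control[i]) next
    g <- graphs[[cls$target_pathway[i]]]
    sink <- g$sinks[min(cls$target_sink[i], length(g$sinks))]
    branch <- if (identical(cls$branch_mode[i], "pathway")) {
      sort(g$nodes$node_id)
    } else {
      branch_path(g, sink)
    }
    planted <- sort(unique(unlist(g$nodes$gene_ids[match(branch, g$nodes$node_id)])))
    fc_mult <- if (cls$direction[i] == "down") 1 / cls$effect_size[i] else
      cls$effect_size[i]
    fc <- setNames(rep(1, length(unlist(g$nodes$gene_ids))),
                   unlist(g$nodes$gene_ids))
    fc[planted] <- fc_mult
    w <- map_fc_to_nodes(g, fc)$weights
    psf <- compute_psf(g, w)
    lg <- log2(psf)
    affected <- abs(lg) > 1e-9
    strong <- abs(lg) >= design$truth_min_log2
    class_truth[[cls$class_label[i]]] <- list(
      pathway_id = g$pathway_id,
      target_sink = sink,
      branch_nodes = branch,
      planted_genes = planted,
      direction = cls$direction[i],
      effect_size = cls$effect_size[i],
      sinks = data.frame(
        sink_id = paste0(g$pathway_id, ":", names(psf)[affected],
                         recycle0 = TRUE),
        expected_log2_psf = as.numeric(lg[affected]),
        direction = ifelse(lg[affected] > 0, "up", "down"),
        truth = strong[affected],
        stringsAsFactors = FALSE),
      truth_sinks = paste0(g$pathway_id, ":", names(psf)[strong],
                           recycle0 = TRUE)
    )
  }
  list(classes = class_truth,
       sinks_per_pathway = vapply(graphs, function(g) length(g$sinks), 0))
}

# lexicographically-first source-to-sink path, excluding the sink itself
branch_path <- function(g, sink) {
  path <- character(0)
  cur <- sink
  repeat {
    parents <- sort(g$edges$from[g$edges$to == cur])
    if (length(parents) == 0L) break
    cur <- parents[1]
    path <- c(cur, path)
  }
  path
}

#' Simulate a group-structured expression matrix
#'
#' Baseline per-gene expression is drawn once from a log-normal distribution
#' (meanlog 7, sdlog 1) and shared across samples. Every sample multiplies
#' the baseline by log-normal noise `exp(N(0, noise_sd * ln 2))` (i.e.
#' `noise_sd` is the noise standard deviation on the log2 scale); disease
#' samples additionally multiply the genes of their class's planted branch by
#' the effect size (or its reciprocal for down-deregulation). The output is
#' on linear scale, so the deregulation reaches the PSF step only through
#' the fold-change normalization and the topology — the propagation is
#' genuinely exercised.
#'
#' @param design A [synthetic_design()].
#' @param graphs Named list of `PathwayGraph` from [generate_pathways()].
#' @param truth Ground truth from [generate_pathways()].
#' @return List with `values` (gene x sample linear-scale matrix), `sheet`
#'   (sample sheet data frame) and `truth` (passed through).
#' @export
simulate_expression <- function(design, graphs, truth) {
  genes <- sort(unique(unlist(lapply(graphs, function(g) unlist(g$nodes$gene_ids)))))
  baseline <- with_seed(derive_seed(design$seed, 100003), {
    setNames(stats::rlnorm(length(genes), meanlog = 7, sdlog = 1), genes)
  })
  cls <- design$classes
  cols <- list()
  sample_ids <- character(0)
  class_labels <- character(0)
  for (i in seq_len(nrow(cls))) {
    lab <- cls$class_label[i]
    n <- cls$n_samples[i]
    effect <- rep(1, length(genes))
    names(effect) <- genes
    if (!cls$is_control[i]) {
      tr <- truth$classes[[lab]]
      mult <- if (tr$direction == "down") 1 / tr$effect_size else tr$effect_size
      effect[tr$planted_genes] <- mult
    }
    noise <- with_seed(derive_seed(design$seed, 200003 + i), {
      matrix(stats::rnorm(length(genes) * n, 0, design$noise_sd * log(2)),
             nrow = length(genes))
    })
    cols[[lab]] <- baseline * effect * exp(noise)
    ids <- sprintf("%s_s%02d", lab, seq_len(n))
    sample_ids <- c(sample_ids, ids)
    class_labels <- c(class_labels, rep(lab, n))
  }
  values <- do.call(cbind, cols)
  colnames(values) <- sample_ids
  rownames(values) <- genes
  sheet <- data.frame(sample_id = sample_ids, class_label = class_labels,
                      dataset_id = "synthetic1",
                      is_control = class_labels ==
                        cls$class_label[cls$is_control],
                      stringsAsFactors = FALSE)
  list(values = values, sheet = sheet, truth = truth)
}

#' Write a complete synthetic study to disk
#'
#' Materializes a [synthetic_design()] as the on-disk inputs the pipeline
#' consumes: `pathways/*.xml` (KGML), `expression.tsv`, `samples.tsv` and
#' `truth.json` under one output directory.
#'
#' @param design A [synthetic_design()] (or a path to a JSON file of its
#'   fields).
#' @param out_dir Output directory (created if needed).
#' @return The output directory, invisibly.
#' @export
simulate_study <- function(design, out_dir) {
  if (is.character(design)) {
    design <- do.call(synthetic_design,
                      jsonlite::fromJSON(design, simplifyVector = TRUE))
  }
  dir.create(file.path(out_dir, "pathways"), recursive = TRUE,
             showWarnings = FALSE)
  pw <- generate_pathways(design)
  for (pid in names(pw$kgml)) {
    writeLines(pw$kgml[[pid]], file.path(out_dir, "pathways",
                                         paste0(pid, ".xml")))
  }
  sim <- simulate_expression(design, pw$graphs, pw$truth)
  write_matrix_tsv(sim$values, file.path(out_dir, "expression.tsv"),
                   id_col = "gene_id")
  utils::write.table(sim$sheet, file.path(out_dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(pw$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
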