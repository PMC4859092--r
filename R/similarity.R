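#' Hierarchical clustering of class profiles
#'
#' Average-linkage clustering of class-level meta-PSF (or PSF) profiles under
#' either a correlation distance (`1 - Pearson r`) or the Euclidean distance.
#'
#' @param class_profiles Class x feature numeric matrix with class labels as
#'   rownames (at least 3 classes).
#' @param metric `"pearson"` (distance `1 - r`) or `"euclidean"`.
#' @return An `hclust` object (labels = class labels).
#' @export
hierarchical_cluster <- function(class_profiles,
                                 metric = c("pearson", "euclidean")) {
  metric <- match.arg(metric)
  m <- as.matrix(class_profiles)
  if (nrow(m) < 3L) stop("need at least 3 classes")
  if (metric == "pearson") {
    sds <- apply(m, 1, stats::sd)
    if (any(sds == 0)) {
      stop("constant class profile(s) under Pearson metric: ",
           paste(rownames(m)[sds == 0], collapse = ", "))
    }
    d <- stats::as.dist(1 - stats::cor(t(m)))
  } else {
    d <- stats::dist(m)
  }
  hc <- stats::hclust(d, method = "average")
  # deterministic leaf order: reorder by label at equal heights
  hc$labels <- rownames(m)
  hc
}

#' Class labels on each side of the first dendrogram split
#'
#' @param hc An `hclust` object.
#' @return List of two character vectors (label sets of the two top
#'   branches).
#' @export
first_split <- function(hc) {
  k2 <- stats::cutree(hc, k = 2)
  split(names(k2), k2)
}

#' Export a dendrogram as Newick text
#'
#' @param hc An `hclust` object.
#' @param path Optional output file.
#' @return Newick string (invisibly when written).
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  tree <- ape::as.phylo(hc)
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Second-level SOM: map class profiles onto a small grid
#'
#' Trains a SOM on class-level profiles (classes as observations) and places
#' each class at its best-matching unit, visualizing between-class diversity.
#'
#' @param class_profiles Class x feature matrix, class labels as rownames (at
#'   least 4 classes).
#' @param grid_rows,grid_cols Small grid (default 4 x 4).
#' @param seed RNG seed.
#' @param ... Further arguments passed to [train_som()].
#' @return Data frame with columns `class_label`, `unit`, `row`, `col`.
#' @export
second_level_som <- function(class_profiles, grid_rows = 4, grid_cols = 4,
                             seed = 1, ...) {
  m <- as.matrix(class_profiles)
  if (nrow(m) < 4L) stop("need at least 4 classes")
  model <- train_som(m, grid_rows = grid_rows, grid_cols = grid_cols,
                     seed = seed, ...)
  u <- model$assignment
  data.frame(class_label = rownames(m), unit = as.integer(u),
             row = model$grid$row[u], col = model$grid$col[u],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Independent component analysis of class profiles
#'
#' FastICA (symmetric decorrelation, logcosh contrast) on the class x feature
#' matrix after centering and PCA whitening. For determinism the unmixing
#' initialization is a seeded random orthonormal matrix and each component's
#' sign is fixed so that its largest-magnitude feature loading is positive.
#'
#' @param class_profiles Class x feature matrix with class labels as
#'   rownames.
#' @param n_components Number of components (at most `n_classes - 1`).
#' @param seed RNG seed.
#' @param max_iter,tol FastICA iteration controls.
#' @return List with `scores` (class x component matrix, columns `IC1`...),
#'   `loadings` (component x feature matrix) and `converged` flag.
#' @export
run_ica <- function(class_profiles, n_components = 3, seed = 1,
                    max_iter = 500, tol = 1e-8) {
  X <- as.matrix(class_profiles)
  n <- nrow(X)
  if (n_components > n - 1L) stop("n_components must be <= n_classes - 1")
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  pos <- sv$d > max(sv$d) * 1e-10
  if (sum(pos) < n_components) {
    stop("degenerate rank: only ", sum(pos),
         " non-null dimensions for ", n_components, " components")
  }
  # PCA-whitened data: rows are observations with unit covariance
  K <- sv$u[, which(pos)[seq_len(n_components)], drop = FALSE] * sqrt(n)
  Zw <- t(K)                                         # n_components x n_obs

  W <- with_seed(seed, matrix(rnorm(n_components * n_components),
                              n_components, n_components))
  W <- sym_decorrelate(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Zw                       # comp x obs
    G <- tanh(WZ)
    Gp <- 1 - G^2
    W_new <- (G %*% t(Zw)) / n - diag(rowMeans(Gp), n_components) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(rowSums(W_new * W)) - 1))
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
  }
  S <- t(W %*% Zw)                       # obs x comp, unit variance
  # loadings of each component on the original features
  loadings <- t(S) %*% Xc / n
  # sign convention: largest-magnitude loading positive
  for (k in seq_len(n_components)) {
    j <- which.max(abs(loadings[k, ]))
    if (loadings[k, j] < 0) {
      loadings[k, ] <- -loadings[k, ]
      S[, k] <- -S[, k]
    }
  }
  dimnames(S) <- list(rownames(X), paste0("IC", seq_len(n_components)))
  rownames(loadings) <- paste0("IC", seq_len(n_components))
  colnames(loadings) <- colnames(X)
  list(scores = S, loadings = loadings, converged = converged)
}

sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)),
                     length(e$values)) %*% t(e$vectors) %*% W
}

#' Build the disease co-regulation graph
#'
#' Nodes are disease classes; two classes are connected when at least one
#' pathway is significantly deregulated in the same direction (sign of the
#' log fold difference versus healthy) in both, with the edge weight counting
#' those co-regulated pathways. `level = "sink"` counts shared sinks instead
#' of pathways.
#'
#' @param diff_results Named list of data frames from [differential_psf()]
#'   (one per disease class; names = class labels).
#' @param level Count co-regulated `"pathway"`s (default) or `"sink"`s.
#' @return An undirected `igraph` graph with all classes as vertices and
#'   integer `weight` edge attribute.
#' @export
build_disease_graph <- function(diff_results, level = c("pathway", "sink")) {
  level <- match.arg(level)
  classes <- names(diff_results)
  if (is.null(classes) || any(!nzchar(classes))) {
    stop("diff_results must be a named list (class labels)")
  }
  sig_sets <- lapply(diff_results, function(d) {
    d <- d[d$significant & d$delta != 0, , drop = FALSE]
    data.frame(key = if (level == "pathway") d$pathway_id else d$sink_id,
               dir = sign(d$delta), stringsAsFactors = FALSE)
  })
  from <- character(0); to <- character(0); wt <- integer(0)
  if (length(classes) >= 2) {
    for (i in seq_len(length(classes) - 1)) for (j in seq(i + 1, length(classes))) {
      a <- sig_sets[[i]]; b <- sig_sets[[j]]
      shared <- merge(a, b, by = c("key", "dir"))
      cnt <- length(unique(shared$key))
      if (cnt >= 1L) {
        from <- c(from, classes[i]); to <- c(to, classes[j])
        wt <- c(wt, cnt)
      }
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(classes), name = classes)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to), weight = wt)
  }
  g
}

#' Walktrap communities of the disease graph
#'
#' Pons-Latapy random-walk community detection on the weighted disease graph
#' (short random walks of length `steps` define vertex proximity; merges are
#' chosen agglomeratively and the maximum-modularity partition is returned).
#' Classes without any co-regulation edge form singleton communities.
#'
#' @param graph `igraph` graph from [build_disease_graph()].
#' @param steps Random-walk length (default 4).
#' @return Named integer vector of community ids (names = class labels),
#'   with attribute `modularity`.
#' @export
walktrap_communities <- function(graph, steps = 4) {
  if (igraph::vcount(graph) == 0L) stop("empty disease graph")
  if (igraph::ecount(graph) == 0L) {
    warning("disease graph has no edges: every class is a singleton community")
    out <- setNames(seq_len(igraph::vcount(graph)),
                    igraph::V(graph)$name)
    attr(out, "modularity") <- 0
    return(out)
  }
  wt <- igraph::cluster_walktrap(graph, weights = igraph::E(graph)$weight,
                                 steps = steps)
  out <- igraph::membership(wt)
  out <- setNames(as.integer(out), names(out))
  attr(out, "modularity") <- max(wt$modularity)
  out
}

#' Write the disease graph as an edge-list TSV and GraphML
#'
#' @param graph `igraph` disease graph.
#' @param tsv_path Path for the edge list (`class_a`, `class_b`, `weight`).
#' @param graphml_path Optional GraphML output path.
#' @return `tsv_path`, invisibly.
#' @export
write_disease_graph <- function(graph, tsv_path, graphml_path = NULL) {
  el <- igraph::as_edgelist(graph)
  df <- data.frame(class_a = el[, 1], class_b = el[, 2],
                   weight = if (igraph::ecount(graph)) igraph::E(graph)$weight
                            else integer(0),
                   stringsAsFactors = FALSE)
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path)) {
    igraph::write_graph(graph, graphml_path, format = "graphml")
  }
  invisible(tsv_path)
}
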