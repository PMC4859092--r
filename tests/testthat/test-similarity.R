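# class x feature profiles with two planted super-groups
super_group_profiles <- function(n_per = 4, n_feat = 30, seed = 1) {
  set.seed(seed)
  sig1 <- c(rep(2, n_feat / 2), rep(0, n_feat / 2))
  sig2 <- c(rep(0, n_feat / 2), rep(2, n_feat / 2))
  x <- rbind(
    t(replicate(n_per, sig1 + rnorm(n_feat, 0, 0.3))),
    t(replicate(n_per, sig2 + rnorm(n_feat, 0, 0.3)))
  )
  rownames(x) <- c(paste0("ca", seq_len(n_per)), paste0("in", seq_len(n_per)))
  x
}

test_that("identical classes merge first; Pearson ignores scaling", {
  x <- super_group_profiles(n_per = 2, seed = 3)
  x <- rbind(x, dup = x["ca1", ])
  hc <- hierarchical_cluster(x, "euclidean")
  first_pair <- sort(c(hc$labels[-hc$merge[1, 1]], hc$labels[-hc$merge[1, 2]]))
  expect_equal(sort(first_pair), c("ca1", "dup"))
  expect_equal(hc$height[1], 0)

  hp1 <- hierarchical_cluster(x, "pearson")
  x2 <- x
  x2["in1", ] <- 2 * x2["in1", ]
  hp2 <- hierarchical_cluster(x2, "pearson")
  expect_equal(hp1$merge, hp2$merge)
  expect_equal(hp1$height, hp2$height, tolerance = 1e-12)

  xc <- x
  xc["ca2", ] <- 1                 # constant profile
  expect_error(hierarchical_cluster(xc, "pearson"), "constant")
})

test_that("the first split separates planted super-groups under both metrics", {
  x <- super_group_profiles(seed = 11)
  for (metric in c("pearson", "euclidean")) {
    hc <- hierarchical_cluster(x, metric)
    fs <- first_split(hc)
    sides <- lapply(fs, function(s) sort(unique(substr(s, 1, 2))))
    expect_setequal(unlist(sides), c("ca", "in"))
    expect_equal(lengths(sides), c(`1` = 1L, `2` = 1L))
  }
})

test_that("dendrogram heights are non-decreasing and export to Newick", {
  x <- super_group_profiles(seed = 21)
  hc <- hierarchical_cluster(x, "euclidean")
  expect_true(all(diff(hc$height) >= -1e-12))
  nwk <- dendrogram_newick(hc)
  expect_match(nwk, "^\\(")
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, rownames(x))
})

test_that("second-level SOM separates super-groups and repeats under a seed", {
  x <- super_group_profiles(seed = 31)
  pos1 <- second_level_som(x, grid_rows = 4, grid_cols = 4, seed = 9)
  pos2 <- second_level_som(x, grid_rows = 4, grid_cols = 4, seed = 9)
  expect_identical(pos1, pos2)
  grp <- substr(pos1$class_label, 1, 2)
  within <- c(dist(pos1[grp == "ca", c("row", "col")]),
              dist(pos1[grp == "in", c("row", "col")]))
  between <- as.matrix(dist(pos1[, c("row", "col")]))[grp == "ca", grp == "in"]
  expect_gt(mean(between), mean(within))

  # identical classes land on the same unit
  xx <- x[c(1, 1, 2, 3), ]
  rownames(xx) <- paste0("c", 1:4)
  pos3 <- second_level_som(xx, grid_rows = 3, grid_cols = 3, seed = 2)
  expect_equal(pos3$unit[1], pos3$unit[2])
})

test_that("ICA recovers independent sources and separates super-groups", {
  # classic two-source recovery: X = S A with independent uniform sources
  set.seed(12)
  n <- 200
  S <- cbind(runif(n, -1, 1), runif(n, -1, 1))
  A <- rbind(c(2, 1, 0.5, 1.5), c(-1, 2, 1, 0.3))
  X <- S %*% A
  rownames(X) <- paste0("obs", 1:n)
  res <- run_ica(X, n_components = 2, seed = 4)
  cors <- abs(cor(res$scores, S))
  best <- apply(cors, 2, max)
  expect_true(all(best >= 0.9))

  # determinism
  res2 <- run_ica(X, n_components = 2, seed = 4)
  expect_identical(res$scores, res2$scores)

  # super-group separation by at least one component (clear group signal)
  set.seed(41)
  sig1 <- c(rep(2, 15), rep(0, 15))
  sig2 <- c(rep(0, 15), rep(2, 15))
  x <- rbind(t(replicate(8, sig1 + rnorm(30, 0, 0.15))),
             t(replicate(8, sig2 + rnorm(30, 0, 0.15))))
  rownames(x) <- c(paste0("ca", 1:8), paste0("in", 1:8))
  ic <- run_ica(x, n_components = 3, seed = 1)
  grp <- substr(rownames(x), 1, 2)
  separated <- vapply(1:3, function(k) {
    a <- ic$scores[grp == "ca", k]; b <- ic$scores[grp == "in", k]
    max(a) < min(b) || max(b) < min(a)
  }, logical(1))
  expect_true(any(separated))

  expect_error(run_ica(x, n_components = nrow(x)), "n_classes - 1")
  expect_error(run_ica(matrix(1, 5, 4), n_components = 2), "degenerate rank")
})

test_that("disease-graph edges count same-direction co-regulated pathways", {
  mk_diff <- function(sinks, pathways, deltas, sig) {
    data.frame(sink_id = sinks, pathway_id = pathways, delta = deltas,
               t_shrink = 1, p_value = 0.01, q_value = 0.1,
               significant = sig, stringsAsFactors = FALSE)
  }
  sinks <- paste0("pw", 1:5, ":s1")
  pws <- paste0("pw", 1:5)
  dA <- mk_diff(sinks, pws, rep(1, 5), rep(TRUE, 5))
  dB <- mk_diff(sinks, pws, rep(1, 5), rep(TRUE, 5))
  g <- build_disease_graph(list(A = dA, B = dB))
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 5)

  # same sinks but opposite direction: no co-regulation
  dC <- mk_diff(sinks, pws, rep(-1, 5), rep(TRUE, 5))
  g2 <- build_disease_graph(list(A = dA, C = dC))
  expect_equal(igraph::ecount(g2), 0)
  expect_equal(igraph::vcount(g2), 2)

  # shared deregulation only between A and B out of three classes
  dE <- mk_diff(sinks, pws, rep(1, 5), rep(FALSE, 5))
  g3 <- build_disease_graph(list(A = dA, B = dB, E = dE))
  el <- igraph::as_edgelist(g3)
  expect_equal(nrow(el), 1)
  expect_setequal(as.vector(el), c("A", "B"))

  # sink-level counting can exceed pathway-level counting
  sinks2 <- c("pw1:s1", "pw1:s2", "pw2:s1")
  dF <- mk_diff(sinks2, c("pw1", "pw1", "pw2"), rep(1, 3), rep(TRUE, 3))
  gp <- build_disease_graph(list(A = dF, B = dF), level = "pathway")
  gs <- build_disease_graph(list(A = dF, B = dF), level = "sink")
  expect_equal(igraph::E(gp)$weight, 2)
  expect_equal(igraph::E(gs)$weight, 3)
})

test_that("walktrap finds cliques, blocks and singleton outliers", {
  # two disconnected cliques
  g <- igraph::make_full_graph(4) + igraph::make_full_graph(4)
  igraph::V(g)$name <- paste0("c", 1:8)
  igraph::E(g)$weight <- 1
  comm <- walktrap_communities(g)
  expect_equal(length(unique(comm)), 2)
  expect_equal(length(unique(comm[1:4])), 1)
  expect_equal(length(unique(comm[5:8])), 1)

  # an isolated class forms its own community
  g2 <- igraph::add_vertices(g, 1, name = "lonely")
  comm2 <- walktrap_communities(g2)
  expect_equal(sum(comm2 == comm2[["lonely"]]), 1)

  expect_error(walktrap_communities(igraph::make_empty_graph(0)), "empty")

  # planted partition: 4 blocks, p_in 0.9, p_out 0.1, mean ARI over 20 seeds
  aris <- vapply(1:20, function(seed) {
    set.seed(seed)
    blocks <- rep(1:4, each = 6)
    n <- length(blocks)
    adj <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      p <- if (blocks[i] == blocks[j]) 0.9 else 0.1
      adj[i, j] <- adj[j, i] <- as.integer(runif(1) < p)
    }
    gp <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::V(gp)$name <- paste0("v", 1:n)
    igraph::E(gp)$weight <- 1
    ari(walktrap_communities(gp), blocks)
  }, 0)
  expect_gte(mean(aris), 0.9)
})

test_that("modularity of the returned partition beats all-singletons", {
  set.seed(3)
  g <- igraph::sample_gnp(15, 0.4)
  igraph::V(g)$name <- paste0("v", 1:15)
  igraph::E(g)$weight <- sample(1:3, igraph::ecount(g), replace = TRUE)
  comm <- walktrap_communities(g)
  mod_single <- igraph::modularity(g, seq_len(15),
                                   weights = igraph::E(g)$weight)
  expect_gte(attr(comm, "modularity"), mod_single)
})
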