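# Shared fixtures: tiny hand-built pathway graphs and KGML documents.

toy_kgml <- function() {
  paste0(
    '<?xml version="1.0"?>\n',
    '<pathway name="path:toy01" title="Toy pathway">\n',
    '  <entry id="A" name="g1" type="gene"><graphics name="A"/></entry>\n',
    '  <entry id="B" name="g2" type="gene"><graphics name="B"/></entry>\n',
    '  <entry id="C" name="g3" type="gene"><graphics name="C"/></entry>\n',
    '  <relation entry1="A" entry2="B" type="PPrel">',
    '<subtype name="activation"/></relation>\n',
    '  <relation entry1="B" entry2="C" type="PPrel">',
    '<subtype name="inhibition"/></relation>\n',
    '</pathway>'
  )
}

# an unbranched activation chain A -> B -> ... with one gene per node
chain_graph <- function(n, signs = rep(1L, n - 1), pid = "chain") {
  ids <- sprintf("n%02d", seq_len(n))
  nodes <- data.frame(node_id = ids, node_kind = "gene",
                      label = ids, stringsAsFactors = FALSE)
  nodes$gene_ids <- lapply(seq_len(n), function(i) sprintf("%s_g%d", pid, i))
  edges <- data.frame(from = ids[-n], to = ids[-1], sign = signs,
                      subtype = "", stringsAsFactors = FALSE)
  pathway_graph(pid, pid, nodes, edges)
}

# diamond A -> {B, C} -> D
diamond_graph <- function() {
  nodes <- data.frame(node_id = c("A", "B", "C", "D"), node_kind = "gene",
                      label = c("A", "B", "C", "D"), stringsAsFactors = FALSE)
  nodes$gene_ids <- list("gA", "gB", "gC", "gD")
  edges <- data.frame(from = c("A", "A", "B", "C"),
                      to = c("B", "C", "D", "D"),
                      sign = 1L, subtype = "", stringsAsFactors = FALSE)
  pathway_graph("diamond", "diamond", nodes, edges)
}

unit_fc <- function(graph) {
  genes <- unlist(graph$nodes$gene_ids)
  setNames(rep(1, length(genes)), genes)
}

# small random layered collection via the generator
random_collection <- function(n_pathways, seed, ...) {
  d <- synthetic_design(n_pathways = n_pathways, seed = seed,
                        classes = data.frame(
                          class_label = c("HC", "D1"),
                          target_pathway = c(NA, 1), target_sink = c(NA, 1),
                          direction = c(NA, "up"), effect_size = c(1, 2),
                          n_samples = c(2, 2), is_control = c(TRUE, FALSE)),
                        ...)
  generate_pathways(d)
}

# adjusted Rand index between two labelings (independent of the package)
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
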