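toy_edges <- function() {
  data.table(gene_a = c("A", "B", "B"), gene_b = c("B", "C", "D"),
             score = c(0.9, 0.5, 0.3))
}

test_that("select_nodes applies strict p and log2FC filters, directionally", {
  de <- data.table(gene = c("keep", "p_fail", "boundary", "down"),
                   log2fc = c(1.6, 3.0, 1.5, -3.0),
                   p_raw = c(0.04, 0.06, 0.01, 0.01),
                   p_adj = c(0.04, 0.06, 0.01, 0.01))
  expect_equal(select_nodes(de), "keep")
  expect_equal(select_nodes(de, p_col = "p_raw"), "keep")
})

test_that("as_interaction_edges canonicalizes undirected edges", {
  raw <- data.table(gene_a = c("B", "A", "A"), gene_b = c("A", "B", "A"),
                    score = c(0.5, 0.7, 0.9))
  expect_warning(out <- as_interaction_edges(raw), "self-loop")
  expect_equal(nrow(out), 1L)
  expect_equal(out$gene_a, "A")
  expect_equal(out$score, 0.7) # duplicate collapsed to max
  expect_error(as_interaction_edges(data.table(gene_a = "A", gene_b = "B",
                                               score = 1.2)), "0, 1")
})

test_that("build_network induces the score-filtered subgraph with isolates", {
  g <- build_network(c("A", "B", "C"), toy_edges(), min_score = 0.4)
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 2L) # B-D outside, B-C passes, 0.3 filtered
  # edge to a non-selected gene is dropped and counted
  expect_equal(igraph::graph_attr(g, "n_dropped_outside"), 1L)
  empty <- build_network(character(0), toy_edges())
  expect_equal(igraph::vcount(empty), 0L)
  # filter at min_score: (A,B,0.3) and (B,C,0.5) at min 0.4 keeps one edge
  g2 <- build_network(c("A", "B", "C"),
                      data.table(gene_a = c("A", "B"), gene_b = c("B", "C"),
                                 score = c(0.3, 0.5)), min_score = 0.4)
  expect_equal(igraph::ecount(g2), 1L)
})

test_that("connectivity_stats computes E/N and the total connection score", {
  g <- build_network(c("A", "B"),
                     data.table(gene_a = "A", gene_b = "B", score = 0.9))
  s <- connectivity_stats(g)
  expect_equal(s$edges_per_node, 0.5)
  expect_equal(s$total_connection_score, 0.9)
  # triangle with scores 0.5
  tri <- build_network(c("A", "B", "C"),
                       data.table(gene_a = c("A", "A", "B"),
                                  gene_b = c("B", "C", "C"), score = 0.5))
  st <- connectivity_stats(tri)
  expect_equal(st$edges_per_node, 1)
  expect_equal(st$total_connection_score, 1.5)
  expect_equal(connectivity_stats(tri, edges_per_node = "mean_degree")$edges_per_node, 2)
  # empty graph: zeros, flagged
  e <- connectivity_stats(build_network(character(0), toy_edges()))
  expect_equal(unlist(e[c("n_nodes", "n_edges", "edges_per_node",
                          "total_connection_score")]),
               c(n_nodes = 0, n_edges = 0, edges_per_node = 0,
                 total_connection_score = 0))
  expect_true(e$flagged)
})

test_that("stats are order-invariant and respond correctly to perturbations", {
  edges <- toy_edges()
  g1 <- build_network(c("A", "B", "C", "D"), edges)
  g2 <- build_network(c("D", "C", "B", "A"), edges[c(3, 1, 2)])
  s1 <- connectivity_stats(g1); s2 <- connectivity_stats(g2)
  expect_equal(s1[1:4], s2[1:4])
  # adding an isolated node strictly decreases E/N when E > 0
  g3 <- build_network(c("A", "B", "C", "D", "E"), edges)
  expect_lt(connectivity_stats(g3)$edges_per_node, s1$edges_per_node)
  # total score is monotone non-decreasing as min_score relaxes
  scores <- vapply(c(0.6, 0.4, 0.2), function(ms) {
    connectivity_stats(build_network(c("A", "B", "C", "D"), edges,
                                     min_score = ms))$total_connection_score
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("module-driven selections are denser than random ones", {
  panel <- small_panel(n_genes = 200L)
  hits <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    edges <- generate_interactions(panel, density = 0.01, seed = 100L + s)
    module_genes <- panel$genes[module == "immune", gene]
    set.seed(200L + s)
    random_genes <- sample(panel$genes$gene, length(module_genes))
    epn_mod <- connectivity_stats(build_network(module_genes, edges))$edges_per_node
    epn_rnd <- connectivity_stats(build_network(random_genes, edges))$edges_per_node
    if (epn_mod > epn_rnd) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)
})
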