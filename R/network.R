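#' Select upregulated target genes for the interaction network
#'
#' Genes significantly upregulated in the focal group: `p < alpha` and
#' `log2fc > lfc_min` (both strict; directional, so downregulated genes are
#' never selected).
#'
#' @param de DE table from [de_test()].
#' @param p_col Which p-value gates selection: `"p_adj"` (default,
#'   consistent with the volcano categories) or `"p_raw"`.
#' @param alpha Significance threshold.
#' @param lfc_min Strict lower bound on log2FC.
#' @return Character vector of selected genes.
#' @export
select_nodes <- function(de, p_col = c("p_adj", "p_raw"), alpha = 0.05,
                         lfc_min = 1.5) {
  p_col <- match.arg(p_col)
  dt <- data.table::as.data.table(de)
  dt[get(p_col) < alpha & log2fc > lfc_min, gene]
}

#' Canonicalize an interaction edge table
#'
#' Undirected edges: endpoints are ordered lexicographically, self-loops
#' dropped, duplicates collapsed to the maximum score, scores validated to
#' lie in (0, 1].
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `score`.
#' @return Deduplicated data.table.
#' @export
as_interaction_edges <- function(edges) {
  dt <- data.table::as.data.table(edges)
  need <- c("gene_a", "gene_b", "score")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("edge table lacks columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(dt$score)) || any(dt$score <= 0) || any(dt$score > 1)) {
    stop("edge scores must lie in (0, 1]")
  }
  n_self <- sum(dt$gene_a == dt$gene_b)
  if (n_self > 0) {
    warning(n_self, " self-loop(s) dropped from edge table")
    dt <- dt[gene_a != gene_b]
  }
  dt[, `:=`(a = pmin(gene_a, gene_b), b = pmax(gene_a, gene_b))]
  out <- dt[, .(score = max(score)), by = .(gene_a = a, gene_b = b)]
  out[]
}

#' Induced interaction subgraph on selected target genes
#'
#' Keeps edges whose both endpoints are selected and whose score is at
#' least `min_score`; isolated selected nodes are retained (they count in
#' the edges-per-node denominator). Edges referencing genes outside the
#' selection are dropped, with the count recorded on the graph.
#'
#' @param nodes Character vector of selected genes.
#' @param edges Edge table (canonicalized via [as_interaction_edges()]).
#' @param min_score Minimum interaction score, default 0.4 (the customary
#'   medium-confidence cut).
#' @return An `igraph` graph with edge attribute `score` and graph
#'   attributes `n_dropped_outside` and `min_score`.
#' @export
build_network <- function(nodes, edges, min_score = 0.4) {
  nodes <- unique(nodes)
  dt <- as_interaction_edges(edges)
  inside <- dt$gene_a %in% nodes & dt$gene_b %in% nodes
  kept <- dt[inside & score >= min_score]
  g <- igraph::graph_from_data_frame(
    kept[, .(from = gene_a, to = gene_b, score = score)],
    directed = FALSE,
    vertices = data.frame(name = nodes))
  g <- igraph::set_graph_attr(g, "n_dropped_outside", sum(!inside))
  igraph::set_graph_attr(g, "min_score", min_score)
}

#' Connectivity statistics of a target-gene interaction network
#'
#' Reports node and edge counts, the edge-to-node ratio ("edges/node",
#' literally E/N; the mean degree 2E/N is available as an alternative
#' convention), and the total connection score, i.e. the sum of the retained
#' edges' interaction scores.
#'
#' @param graph igraph object from [build_network()].
#' @param edges_per_node `"ratio"` for E/N (default) or `"mean_degree"` for
#'   2E/N.
#' @return List with `n_nodes`, `n_edges`, `edges_per_node`,
#'   `total_connection_score`, `convention`, `flagged` (TRUE for the empty
#'   graph, where all stats are zero by convention).
#' @export
connectivity_stats <- function(graph, edges_per_node = c("ratio", "mean_degree")) {
  edges_per_node <- match.arg(edges_per_node)
  n <- igraph::vcount(graph)
  e <- igraph::ecount(graph)
  total <- if (e > 0) sum(igraph::E(graph)$score) else 0
  epn <- if (n == 0) 0 else (if (edges_per_node == "ratio") e / n else 2 * e / n)
  list(n_nodes = n, n_edges = e, edges_per_node = epn,
       total_connection_score = total, convention = edges_per_node,
       flagged = n == 0)
}
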