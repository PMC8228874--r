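#!/usr/bin/env Rscript
# Stage 6: differential expression for the NE and infiltration-phenotype
# contrasts, volcano categorization, target-set overlap and connectivity
# statistics of the induced interaction networks.

suppressPackageStartupMessages({
  library(sclcTME)
  library(data.table)
})

out <- "results/targets"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

samples <- fread("results/sim/samples.tsv")
expr <- read_expression("results/sim/expression.tsv")
edges <- read_edges("results/sim/edges.tsv")
phen <- fread("results/phenotype/phenotypes.tsv")

ne <- setNames(samples$ne_subtype, samples$sample_id)[colnames(expr)]
ph <- setNames(phen$phenotype, phen$sample_id)[colnames(expr)]
ph[!ph %in% c("oasis", "desert")] <- NA

contrasts <- list(
  ne_low_vs_high = list(labels = ne, focal = "NE-low"),
  oasis_vs_desert = list(labels = ph, focal = "oasis"))

stats_rows <- list()
up_sets <- list()
for (nm in names(contrasts)) {
  ctr <- contrasts[[nm]]
  de <- de_test(expr, ctr$labels, focal = ctr$focal)
  fwrite(de, file.path(out, paste0("de_", nm, ".tsv")), sep = "\t")
  message(nm, " volcano categories:")
  print(de[, .N, by = category])
  for (side in c("up", "down")) {
    d <- if (side == "up") de else copy(de)[, log2fc := -log2fc]
    nodes <- select_nodes(d)
    g <- build_network(nodes, edges)
    s <- connectivity_stats(g)
    stats_rows[[paste(nm, side)]] <- data.table(
      contrast = nm, side = side, n_nodes = s$n_nodes, n_edges = s$n_edges,
      edges_per_node = s$edges_per_node,
      total_connection_score = s$total_connection_score)
    if (side == "up") up_sets[[nm]] <- nodes
  }
}
net <- rbindlist(stats_rows)
fwrite(net, file.path(out, "network_stats.tsv"), sep = "\t")
message("network connectivity by contrast and direction:")
print(net)

ov <- target_overlap(up_sets$ne_low_vs_high, up_sets$oasis_vs_desert)
jsonlite::write_json(ov, file.path(out, "target_overlap.json"), auto_unbox = TRUE)
message(sprintf("upregulated-target overlap: %d NE-low-only, %d shared, %d oasis-only",
                length(ov$a_only), length(ov$shared), length(ov$b_only)))
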