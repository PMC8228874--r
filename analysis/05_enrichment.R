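#!/usr/bin/env Rscript
# Stage 5: preranked GSEA per group (NE phenotype and each biomarker's HIGH
# set) and the z-scored pathway-by-group heatmap matrix.

suppressPackageStartupMessages({
  library(sclcTME)
  library(data.table)
})

seed <- 20260928L
out <- "results/enrichment"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

samples <- fread("results/sim/samples.tsv")
expr <- read_expression("results/sim/expression.tsv")
sets <- read_gmt("results/sim/gene_sets.gmt")
ann <- read_annotation("results/phenotype/annotation.csv")

ne <- setNames(samples$ne_subtype, samples$sample_id)
groups <- list("NE-low" = ne == "NE-low", "NE-high" = ne == "NE-high")
for (param in setdiff(names(ann), "sample_id")) {
  groups[[param]] <- setNames(ann[[param]] == "HIGH", ann$sample_id)
}

res <- rbindlist(lapply(seq_along(groups), function(i) {
  ind <- groups[[i]][colnames(expr)]
  labels <- ifelse(ind, "focal", "rest")
  if (sum(labels == "focal", na.rm = TRUE) < 2L ||
      sum(labels == "rest", na.rm = TRUE) < 2L) {
    message("skipping degenerate group: ", names(groups)[i])
    return(NULL)
  }
  run_gsea(expr, labels, sets, group = names(groups)[i], focal = "focal",
           n_perm = 1000L, seed = seed + 10L * i)
}))
fwrite(res, file.path(out, "enrichment.tsv"), sep = "\t")

z <- nes_heatmap_matrix(res, threshold = 1)
write.table(round(z, 3), file.path(out, "nes_heatmap_matrix.tsv"),
            sep = "\t", quote = FALSE, col.names = NA)

message("module pathways by group (NES):")
print(dcast(res[pathway %in% c("immune_response", "cell_proliferation",
                               "neuroendocrine_differentiation") &
                  group %in% c("NE-low", "NE-high", "CD68t", "CD163t")],
            pathway ~ group, value.var = "nes"))
message(sprintf("heatmap matrix: %d pathways passed the |NES| > 1 filter over %d groups",
                nrow(z), ncol(z)))
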