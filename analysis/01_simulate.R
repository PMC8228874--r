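#!/usr/bin/env Rscript
# Stage 1: generate the synthetic cohort at the study conditions.
# Writes the sample table, compartment counts, the 2560-gene expression
# panel, the gene-set collection (GMT) and the interaction edge table.

suppressPackageStartupMessages({
  library(sclcTME)
  library(data.table)
})

seed <- 20260928L
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- cohort_spec(seed = seed)
coh <- generate_cohort(spec)
panel <- panel_spec()
expr <- generate_expression(coh$samples, panel, seed = seed + 1L)
sets <- generate_gene_sets(panel, n_decoys = 20L, seed = seed + 2L)
edges <- generate_interactions(panel, seed = seed + 3L)

fwrite(coh$samples, file.path(out, "samples.tsv"), sep = "\t")
write_counts(coh$counts, file.path(out, "counts.tsv"))
write_expression(expr, file.path(out, "expression.tsv"))
write_gmt(sets, file.path(out, "gene_sets.gmt"))
write_edges(edges, file.path(out, "edges.tsv"))
fwrite(panel$genes, file.path(out, "panel_modules.tsv"), sep = "\t")

message(sprintf("cohort: %d patients, %d samples (%d NE-high primaries)",
                spec$n_patients, nrow(coh$samples),
                coh$samples[site == "primary", sum(ne_subtype == "NE-high")]))
message(sprintf("counts: %d rows; panel: %d genes; %d gene sets; %d edges",
                nrow(coh$counts), nrow(expr), length(sets), nrow(edges)))
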