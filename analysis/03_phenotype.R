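#!/usr/bin/env Rscript
# Stage 3: MAD dichotomization of every (marker, compartment) parameter and
# classification into immune-oasis / immune-desert and macrophage phenotypes.

suppressPackageStartupMessages({
  library(sclcTME)
  library(data.table)
})

out <- "results/phenotype"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

dens <- fread("results/morphometry/densities.tsv")
cd33 <- fread("results/morphometry/cd33_scores.tsv")

ann <- annotate_markers(dens, scores = cd33, c = 0)
phen <- classify_immune_phenotype(ann$annotation)
mac <- macrophage_class(ann$annotation,
                        params = c("CD68s", "CD68t", "CD163s", "CD163t", "CD33s"))

write_annotation(ann$annotation, file.path(out, "annotation.csv"))
fwrite(ann$cutoffs, file.path(out, "cutoffs.tsv"), sep = "\t")
fwrite(phen, file.path(out, "phenotypes.tsv"), sep = "\t")
fwrite(mac, file.path(out, "macrophage_class.tsv"), sep = "\t")

message("MAD cutoffs (c = 0, i.e. median split):")
print(ann$cutoffs)
message("immune phenotype counts:")
print(phen[, .N, by = phenotype])
message("macrophage class counts:")
print(mac[, .N, by = macrophage_class])
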