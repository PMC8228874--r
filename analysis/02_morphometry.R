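#!/usr/bin/env Rscript
# Stage 2: replicate-averaged densities, ordinal CD33 scores, replicate
# concordance (core A vs core B) and immune-cell composition per NE group.

suppressPackageStartupMessages({
  library(sclcTME)
  library(data.table)
})

sim <- "results/sim"
out <- "results/morphometry"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

samples <- fread(file.path(sim, "samples.tsv"))
counts <- read_counts(file.path(sim, "counts.tsv"))

dens <- average_replicates(counts[marker != "CD33"])
cd33 <- cd33_scores(counts[marker == "CD33"])
fwrite(dens, file.path(out, "densities.tsv"), sep = "\t")
fwrite(cd33, file.path(out, "cd33_scores.tsv"), sep = "\t")

## core A vs core B concordance on primary tumors (the justification for
## averaging replicate cores before any downstream statistics)
pri <- samples[site == "primary", sample_id]
core_dens <- counts[sample_id %in% pri & marker != "CD33",
                    .(density = mean(cell_density(cell_count, area_um2))),
                    by = .(sample_id, marker, compartment, core_id)]
wide <- dcast(core_dens, sample_id + marker + compartment ~ core_id,
              value.var = "density")
conc <- wide[, {
  r <- paired_replicate_test(A, B)
  .(W_pos = r$W_pos, W_neg = r$W_neg, p_value = r$p_value, n = r$n_used)
}, by = .(marker, compartment)]
fwrite(conc, file.path(out, "core_concordance.tsv"), sep = "\t")
message("core A vs B signed-rank p-values (none should be small):")
print(conc)

## composition of the CD45+ immune infiltrate, per site and NE group
ne <- setNames(samples$ne_subtype, samples$sample_id)
comp <- rbindlist(lapply(c("primary", "ln"), function(st) {
  ids <- samples[site == st, sample_id]
  cbind(site = st,
        composition(dens[sample_id %in% ids], groups = ne))
}))
fwrite(comp, file.path(out, "composition.tsv"), sep = "\t")
nest <- comp[site == "primary" & compartment == "tumor_nest"]
message("primary tumor-nest composition (fraction of CD45+ density):")
print(dcast(nest, marker ~ group, value.var = "fraction"))
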