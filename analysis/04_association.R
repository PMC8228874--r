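#!/usr/bin/env Rscript
# Stage 4: rank-correlation grid between marker densities in primary tumors
# and NE-low vs NE-high density comparisons (Mann-Whitney U).

suppressPackageStartupMessages({
  library(sclcTME)
  library(data.table)
})

out <- "results/association"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

samples <- fread("results/sim/samples.tsv")
dens <- fread("results/morphometry/densities.tsv")
pri <- samples[site == "primary", sample_id]

grid <- correlation_matrix(dens, method = "spearman", samples = pri)
grid$long[, strength := correlation_strength(estimate)]
fwrite(grid$long, file.path(out, "correlations.tsv"), sep = "\t")
write.table(round(grid$matrix, 3), file.path(out, "correlation_matrix.tsv"),
            sep = "\t", quote = FALSE, col.names = NA)
message("strong primary-tumor correlations (|r_s| > 0.7):")
print(grid$long[abs(estimate) > 0.7][order(-abs(estimate))])

## NE-low vs NE-high comparisons per marker and compartment, both sites
ne <- setNames(samples$ne_subtype, samples$sample_id)
site_of <- setNames(samples$site, samples$sample_id)
dens[, `:=`(ne = ne[sample_id], site = site_of[sample_id])]
cmp <- dens[, {
  r <- two_group_test(density[ne == "NE-low"], density[ne == "NE-high"])
  .(U = r$U_a, p_value = r$p_value, method = r$method,
    mean_ne_low = mean(density[ne == "NE-low"]),
    mean_ne_high = mean(density[ne == "NE-high"]))
}, by = .(site, marker, compartment)]
fwrite(cmp, file.path(out, "ne_comparisons.tsv"), sep = "\t")
message("NE-low vs NE-high density comparisons (primary):")
print(cmp[site == "primary"])
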