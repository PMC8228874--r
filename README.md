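# sclcTME

Compartment-resolved profiling of the tumor immune microenvironment in
small cell lung cancer (SCLC), as an R package plus a numbered analysis
workflow.

Limited-stage SCLC splits into neuroendocrine-high (NE-high, ASCL1/NEUROD1
driven) and NE-low (YAP1/POU2F3) subtypes with starkly different immune
microenvironments. This package implements the full quantitative chain used
to characterize that difference from tissue-microarray (TMA) cell counts
and a targeted expression panel:

1. **Morphometry** — per-core, per-section, per-compartment (stroma vs
   tumor nest) cell counts and measured areas become cell densities
   (cells/mm², `count / (area_µm² × 10⁻⁶)`), replicate sections averaged
   within cores and cores averaged per sample; sparse CD33+ myeloid cells
   are scored ordinally (0: 0 cells, 1: 1–10, 2: 11–20, 3: ≥21).
2. **Phenotyping** — each (marker, compartment) parameter is dichotomized
   at `median + c·MAD` (raw MAD, default `c = 0`); samples are classified
   *immune-oasis* (HIGH for stromal **or** intratumoral CD45 **and** HIGH
   for stromal **or** intratumoral CD3) or *immune-desert* (LOW for both
   CD3 parameters **and** LOW for at least one CD45 parameter), with an
   explicit `ambiguous` remainder.
3. **Association** — Spearman / Kendall tau-b correlation grids between
   marker densities, Mann–Whitney U group comparisons (exact by full
   enumeration for small groups, valid under ties), Wilcoxon signed-rank
   concordance of replicate cores.
4. **Enrichment** — preranked GSEA written from scratch: signal-to-noise
   (or t / log2FC) gene ranking, the weighted Kolmogorov–Smirnov running
   sum `P_hit(i) − P_miss(i)` with `ES = max-deviation`, a gene-label
   permutation null giving NES and nominal p, and the z-scored
   pathway-by-group matrix used for NES heatmaps (pathways kept at
   max |NES| > 1).
5. **Differential + network** — per-gene Welch tests with Bonferroni
   adjustment, volcano categories (`p < 0.05` with |log2FC| > 2 red,
   1.5–2 dark blue, below 1.5 light blue), target selection at `p < 0.05`
   and `log2FC > 1.5`, induced interaction subgraphs (score ≥ 0.4) and
   their connectivity statistics: edges/node (E/N) and total connection
   score (Σ edge scores).
6. **Synthetic cohort generator** — a seeded generator reproducing the
   cohort's statistical structure (32 patients, primary + matched
   lymph-node sample, two cores × two sections for primaries, published
   density group means, a shared latent "infiltration" factor tuned to
   published pooled rank correlations with measurement-error compensation,
   negative-binomial counts, and a 2560-gene panel with immune /
   proliferation / neuroendocrine modules), so the whole pipeline is
   testable without any external data.

## Worked example

```r
library(sclcTME)

spec  <- cohort_spec(seed = 42)            # study-condition defaults
coh   <- generate_cohort(spec)
panel <- panel_spec()                      # 2560-gene panel
expr  <- generate_expression(coh$samples, panel, seed = 43)

res <- run_pipeline(list(
  samples   = coh$samples,
  counts    = coh$counts,
  expression = expr,
  gene_sets = generate_gene_sets(panel, seed = 44),
  edges     = generate_interactions(panel, seed = 45)),
  pipeline_config(seed = 46))

table(res$phenotypes$phenotype)
res$enrichment[pathway == "immune_response" & group %in% c("NE-low", "NE-high")]
res$network_stats$ne_up[c("n_nodes", "edges_per_node", "total_connection_score")]
```

On the default 32-patient cohort this prints, e.g., a phenotype split of
roughly 33 oasis / 20 desert / 11 ambiguous out of 64 samples; a strongly
positive immune-response NES in the NE-low group and a negative one in the
NE-high group (the proliferation set mirrors this); and an NE-low target
network of ~75 genes with an edge-to-node ratio near 2 and a total
connection score near 100. The realized pooled Spearman correlation between
CD68+ and CD163+ tumor-nest densities sits at its 0.76 generator target
(±0.02 at n = 5000 patients), and CD68+ macrophages make up about 62% of
CD45+ cells in NE-low primary tumor nests versus CD3+ T-cells at about 18%
in NE-high nests.

## Analysis workflow

The `analysis/` scripts run the stages end to end on a simulated cohort and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # cohort, counts, panel, gene sets, edges
Rscript analysis/02_morphometry.R       # densities, CD33 scores, composition
Rscript analysis/03_phenotype.R         # MAD cutoffs, annotations, phenotypes
Rscript analysis/04_association.R       # correlation grid, NE comparisons
Rscript analysis/05_enrichment.R        # per-group GSEA, NES heatmap matrix
Rscript analysis/06_targets_networks.R  # DE, volcano, overlaps, networks
```

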