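test_that("generation is bit-identical under a fixed seed", {
  spec <- small_cohort_spec(seed = 99L)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  panel <- small_panel()
  ea <- generate_expression(a$samples, panel, seed = 5L)
  eb <- generate_expression(b$samples, panel, seed = 5L)
  expect_identical(ea, eb)
  expect_identical(generate_interactions(panel, 0.01, seed = 7L),
                   generate_interactions(panel, 0.01, seed = 7L))
  # different seeds give different draws
  expect_false(identical(a$counts,
                         generate_cohort(small_cohort_spec(seed = 100L))$counts))
})

test_that("generated tables satisfy the structural contract", {
  coh <- generate_cohort(small_cohort_spec(n_patients = 8L, seed = 3L))
  expect_equal(nrow(coh$samples), 16L) # primary + LN per patient
  counts <- coh$counts
  expect_true(all(counts$cell_count >= 0))
  expect_true(all(counts$cell_count == round(counts$cell_count)))
  expect_true(all(counts$area_um2 > 0))
  # 2 cores x 2 sections for primaries, 1 core x 2 sections for LN
  layout <- counts[, .(n = .N), by = .(sample_id, marker, compartment)]
  sites <- merge(layout, coh$samples[, .(sample_id, site)], by = "sample_id")
  expect_true(all(sites[site == "primary", n] == 4L))
  expect_true(all(sites[site == "ln", n] == 2L))
})

test_that("the NE-high fraction is realized at scale", {
  coh <- generate_cohort(cohort_spec(n_patients = 10000L,
                                     ne_high_fraction = 0.65, seed = 19L))
  frac <- coh$samples[site == "primary", mean(ne_subtype == "NE-high")]
  expect_lt(abs(frac - 0.65), 0.02)
})

test_that("the pooled CD68/CD163 tumor-nest correlation target is realized", {
  coh <- generate_cohort(cohort_spec(n_patients = 5000L, seed = 23L))
  dens <- average_replicates(coh$counts[marker %in% c("CD68", "CD163")])
  pri <- coh$samples[site == "primary", sample_id]
  w <- dcast(dens[sample_id %in% pri & compartment == "tumor_nest"],
             sample_id ~ marker, value.var = "density")
  rho <- cor(w$CD68, w$CD163, method = "spearman")
  expect_lt(abs(rho - 0.76), 0.05)
})

test_that("unsatisfiable correlation targets are rejected with a diagnostic", {
  # a target this strong cannot survive the NE-group mean adjustment
  bad <- data.table(param_a = "CD68t", param_b = "CD163t", rho = 0.999)
  expect_error(cohort_spec(target_correlations = bad), "unsatisfiable")
  expect_error(cohort_spec(target_correlations = data.table(
    param_a = "CD68t", param_b = "CD163t", rho = 1.2)), "\\[-1, 1\\]")
  expect_error(cohort_spec(target_correlations = data.table(
    param_a = "NOPEt", param_b = "CD163t", rho = 0.5)), "unknown")
})

test_that("expression modules shift by the configured effect size", {
  spec <- cohort_spec(n_patients = 30L, seed = 7L)
  coh <- generate_cohort(spec)
  # the effect-size contract in isolation: no patient or infiltration terms
  panel <- small_panel(effect_size = 2, noise_sd = 0.5, patient_sd = 0,
                       infiltration_coef = 0)
  expr <- generate_expression(coh$samples, panel, seed = 11L)
  ne <- stats::setNames(coh$samples$ne_subtype, coh$samples$sample_id)[colnames(expr)]
  imm <- panel$genes[module == "immune", gene]
  lfc <- rowMeans(expr[imm, ne == "NE-low"]) - rowMeans(expr[imm, ne == "NE-high"])
  expect_lt(abs(mean(lfc) - 2), 0.3)
})

test_that("a zero effect size leaves all module means at the null", {
  coh <- generate_cohort(cohort_spec(n_patients = 40L, seed = 13L))
  panel <- small_panel(effect_size = 0, infiltration_coef = 0)
  expr <- generate_expression(coh$samples, panel, seed = 17L)
  ne <- stats::setNames(coh$samples$ne_subtype, coh$samples$sample_id)[colnames(expr)]
  for (mod in c("immune", "proliferation", "neuroendocrine", "background")) {
    g <- panel$genes[module == mod, gene]
    module_means <- colMeans(expr[g, , drop = FALSE])
    delta <- mean(module_means[ne == "NE-low"]) - mean(module_means[ne == "NE-high"])
    se <- sqrt(var(module_means[ne == "NE-low"]) / sum(ne == "NE-low") +
                 var(module_means[ne == "NE-high"]) / sum(ne == "NE-high"))
    expect_lt(abs(delta), 3 * se)
  }
})

test_that("matched primary/LN profiles share patient-level effects", {
  coh <- generate_cohort(cohort_spec(n_patients = 50L, seed = 29L))
  panel <- small_panel(patient_sd = 1.5)
  expr <- generate_expression(coh$samples, panel, seed = 31L)
  samp <- coh$samples
  pri <- samp[site == "primary"][order(patient_id)]
  ln <- samp[site == "ln"][order(patient_id)]
  mean_pri <- colMeans(expr[, pri$sample_id])
  mean_ln <- colMeans(expr[, ln$sample_id])
  # patient random effect induces correlation of matched sample means
  expect_gt(cor(mean_pri, mean_ln), 0.5)
})

test_that("gene sets are drawn from the panel and interactions respect modules", {
  panel <- small_panel()
  sets <- generate_gene_sets(panel, n_decoys = 5, decoy_size = 10, seed = 2)
  for (s in sets) expect_true(all(s %in% panel$genes$gene))
  expect_setequal(sets$immune_response, panel$genes[module == "immune", gene])
  # zero density: no edges at all
  expect_equal(nrow(generate_interactions(panel, density = 0, seed = 1)), 0L)
  # within-module pair fraction exceeds across-module fraction, 5 seeds
  p200 <- small_panel(n_genes = 200L)
  mod_of <- stats::setNames(p200$genes$module, p200$genes$gene)
  for (s in 1:5) {
    e <- generate_interactions(p200, density = 0.02, seed = 50L + s)
    same <- mod_of[e$gene_a] == mod_of[e$gene_b] & mod_of[e$gene_a] != "background"
    k <- table(p200$genes$module)
    n_within <- sum(k[setdiff(names(k), "background")] *
                      (k[setdiff(names(k), "background")] - 1) / 2)
    n_total <- nrow(p200$genes) * (nrow(p200$genes) - 1) / 2
    frac_within <- sum(same) / n_within
    frac_across <- sum(!same) / (n_total - n_within)
    expect_gt(frac_within, frac_across)
  }
})

test_that("calibrated genes reproduce their pinned group means", {
  coh <- generate_cohort(cohort_spec(n_patients = 300L, seed = 37L))
  panel <- panel_spec(n_genes = 400L,
                      module_sizes = c(immune = 60L, proliferation = 40L,
                                       neuroendocrine = 20L))
  expr <- generate_expression(coh$samples, panel, seed = 41L)
  ne <- stats::setNames(coh$samples$ne_subtype, coh$samples$sample_id)[colnames(expr)]
  cal <- default_calibrated_genes()
  for (i in seq_len(nrow(cal))) {
    expect_lt(abs(mean(expr[cal$gene[i], ne == "NE-low"]) - cal$mean_ne_low[i]), 0.2)
    expect_lt(abs(mean(expr[cal$gene[i], ne == "NE-high"]) - cal$mean_ne_high[i]), 0.2)
  }
})
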