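test_that("mad_cutoff is median + c * raw MAD", {
  expect_equal(mad_cutoff(c(1, 2, 3, 4, 100), c = 0)$threshold, 3)
  # median 3, |x - 3| = (2,1,0,1,97), MAD 1
  ct <- mad_cutoff(c(1, 2, 3, 4, 100), c = 2)
  expect_equal(ct$mad, 1)
  expect_equal(ct$threshold, 5)
  expect_warning(mad_cutoff(rep(7, 5)), "identical")
  expect_error(mad_cutoff(3), "at least 2")
})

test_that("mad_cutoff threshold is equivariant under increasing affine maps", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(15); a <- runif(1, 0.1, 5); b <- rnorm(1); cc <- runif(1, 0, 3)
    expect_equal(mad_cutoff(a * x + b, c = cc)$threshold,
                 a * mad_cutoff(x, c = cc)$threshold + b)
  }
})

test_that("dichotomize: strict threshold for densities, score >= 2 for ordinals", {
  ct <- mad_cutoff(c(1, 2, 3, 4, 5))
  expect_equal(dichotomize(c(2, 3, 3.01), ct), c("LOW", "LOW", "HIGH"))
  expect_equal(dichotomize(0:3, ordinal = TRUE),
               c("LOW", "LOW", "HIGH", "HIGH"))
  expect_equal(dichotomize(c(1, NA, 4), ct), c("LOW", NA, "HIGH"))
})

test_that("dichotomization is monotone in the value", {
  ct <- mad_cutoff(c(10, 20, 30, 40), c = 1)
  vals <- seq(0, 60, by = 0.5)
  calls <- dichotomize(vals, ct)
  # once HIGH, always HIGH for larger values
  expect_true(all(diff(calls == "HIGH") >= 0))
})

test_that("oasis/desert classifier matches the truth-table oracle on all 16 combinations", {
  combos <- expand.grid(CD45s = c("HIGH", "LOW"), CD45t = c("HIGH", "LOW"),
                        CD3s = c("HIGH", "LOW"), CD3t = c("HIGH", "LOW"),
                        stringsAsFactors = FALSE)
  ann <- data.table(sample_id = sprintf("s%02d", seq_len(nrow(combos))), combos)
  got <- classify_immune_phenotype(ann)
  want <- mapply(oracle_phenotype, combos$CD45s, combos$CD45t,
                 combos$CD3s, combos$CD3t)
  expect_equal(got$phenotype, unname(want))
  # the two rules never both fire
  expect_false(any(got$phenotype == "oasis" & want == "desert"))
  expect_setequal(unique(got$phenotype), c("oasis", "desert", "ambiguous"))
})

test_that("classifier handles quoted example calls and missing inputs", {
  ann <- data.table(sample_id = c("oasis_ex", "desert_ex", "ambig_ex", "na_ex"),
                    CD45s = c("HIGH", "LOW", "HIGH", NA),
                    CD45t = c("LOW", "LOW", "HIGH", "HIGH"),
                    CD3s = c("HIGH", "LOW", "LOW", "HIGH"),
                    CD3t = c("LOW", "LOW", "LOW", "HIGH"))
  out <- classify_immune_phenotype(ann)
  expect_equal(out$phenotype, c("oasis", "desert", "ambiguous", "ambiguous"))
  expect_match(out$reason[4], "missing")
  expect_error(classify_immune_phenotype(ann[, .(sample_id, CD45s)]), "required")
})

test_that("macrophage_class applies the at-least-half rule over available calls", {
  ann <- data.table(sample_id = c("all_high", "all_low", "three_high"),
                    CD68s = c("HIGH", "LOW", "HIGH"),
                    CD68t = c("HIGH", "LOW", "HIGH"),
                    CD163s = c("HIGH", "LOW", "HIGH"),
                    CD163t = c("HIGH", "LOW", "LOW"),
                    CD33s = c("HIGH", "LOW", "LOW"),
                    MHCIIt = c("HIGH", "LOW", "LOW"))
  out <- macrophage_class(ann)
  expect_equal(out$macrophage_class,
               c("macrophage_high", "macrophage_low", "macrophage_high"))
  # all calls missing is an error
  bad <- data.table(sample_id = "x", CD68s = NA_character_)
  expect_error(macrophage_class(bad), "missing")
})

test_that("annotate_markers produces one HIGH/LOW column per parameter", {
  dens <- CJ(sample_id = sprintf("s%d", 1:6), marker = c("CD45", "CD3"),
             compartment = c("stroma", "tumor_nest"))
  set.seed(3)
  dens[, density := rlnorm(.N, 4, 1)]
  ann <- annotate_markers(dens, c = 0)
  expect_setequal(setdiff(names(ann$annotation), "sample_id"),
                  c("CD45s", "CD45t", "CD3s", "CD3t"))
  # median split: strictly-above-median values are HIGH
  for (p in ann$cutoffs$param) {
    thr <- ann$cutoffs[param == p, threshold]
    sub <- dens[paste0(marker, ifelse(compartment == "stroma", "s", "t")) == p]
    expect_equal(ann$annotation[[p]][match(sub$sample_id, ann$annotation$sample_id)],
                 ifelse(sub$density > thr, "HIGH", "LOW"))
  }
})

test_that("phenotype tracks the generating infiltration factor on strong cohorts", {
  # isolate the infiltration factor: NE-neutral density means, strong
  # CD45/CD3 coupling to the shared latent factor
  dm <- default_density_means()
  dm[, mean := mean(mean), by = .(marker, compartment, site)]
  targets <- data.table(param_a = c("CD45s", "CD45t", "CD68t"),
                        param_b = c("CD3s", "CD3t", "CD163t"),
                        rho = c(0.93, 0.93, 0.76))
  coh <- generate_cohort(cohort_spec(n_patients = 60L, density_means = dm,
                                     target_correlations = targets, seed = 21L))
  dens <- average_replicates(coh$counts[marker != "CD33"])
  ann <- annotate_markers(dens)
  ph <- classify_immune_phenotype(ann$annotation)
  merged <- merge(ph, coh$samples, by = "sample_id")
  # a median-split classifier centers at the cohort's median infiltration,
  # so the factor's sign is taken relative to that center
  z_center <- median(merged$latent_infiltration)
  unamb <- merged[phenotype != "ambiguous"]
  agree <- unamb[, mean((phenotype == "oasis") == (latent_infiltration > z_center))]
  expect_gt(agree, 0.9)
})
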