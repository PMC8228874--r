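ranked_fixture <- function(scores, genes = sprintf("g%02d", seq_along(scores))) {
  data.table(gene = genes, score = scores)
}

test_that("rank_genes scores and orders a two-group contrast", {
  expr <- rbind(ga = c(3, 5, 1, 1), gb = c(2, 2, 2, 2), gc = c(0, 0, 4, 4))
  colnames(expr) <- paste0("s", 1:4)
  labels <- c("A", "A", "B", "B")
  r <- rank_genes(expr, labels, metric = "log2fc", focal = "A")
  expect_equal(r[gene == "ga", score], 3) # mean 4 - mean 1
  expect_equal(r[gene == "gb", score], 0)
  expect_equal(r[gene == "gc", score], -4)
  expect_equal(r$gene, c("ga", "gb", "gc")) # descending
  # identical group means score zero under snr and t
  for (m in c("signal_to_noise", "t_stat")) {
    expect_equal(rank_genes(expr, labels, metric = m)[gene == "gb", score], 0)
  }
  # zero-variance groups stay finite via the sd floor
  zv <- rbind(gz = c(2, 2, 0, 0), gw = c(1, 2, 3, 4))
  colnames(zv) <- paste0("s", 1:4)
  s <- rank_genes(zv, labels, metric = "signal_to_noise")[gene == "gz", score]
  expect_true(is.finite(s))
  expect_equal(s, (2 - 0) / (0.4 + 0.2)) # floors 0.2*|2| and absolute 0.2
})

test_that("rank_genes breaks ties deterministically by gene id", {
  expr <- matrix(rep(c(1, 1, 0, 0), 3), nrow = 3, byrow = TRUE,
                 dimnames = list(c("zz", "aa", "mm"), paste0("s", 1:4)))
  r <- rank_genes(expr, c("A", "A", "B", "B"), metric = "log2fc")
  expect_equal(r$gene, c("aa", "mm", "zz"))
  expect_error(rank_genes(expr, c("A", "A", "A", "B")), "2 samples")
})

test_that("enrichment_score matches trivial single-gene cases", {
  r <- ranked_fixture(c(4, 3, 2, 1))
  expect_equal(enrichment_score(r, "g01", p = 0)$es, 1)
  expect_equal(enrichment_score(r, "g04", p = 0)$es, -1)
  expect_error(enrichment_score(r, "absent"), "disjoint")
  expect_error(enrichment_score(r, r$gene), "universe")
})

test_that("enrichment_score reproduces the five-step hand computation", {
  # scores 5..1, set at ranks 1 and 3, p = 1:
  # +5/8, -1/3, +3/8, -1/3, -1/3 -> curve peaks at 2/3 after rank 3
  r <- ranked_fixture(c(5, 4, 3, 2, 1))
  out <- enrichment_score(r, c("g01", "g03"), p = 1, return_curve = TRUE)
  expect_equal(out$es, 2 / 3)
  expect_equal(out$running_sum,
               cumsum(c(5 / 8, -1 / 3, 3 / 8, -1 / 3, -1 / 3)))
  expect_equal(out$leading_edge, c("g01", "g03"))
})

test_that("running sum ends at zero and ES is invariant to positive rescaling", {
  set.seed(23)
  for (i in 1:50) {
    n <- sample(6:60, 1)
    r <- ranked_fixture(sort(rnorm(n), decreasing = TRUE))
    set <- sample(r$gene, sample(1:(n - 1), 1))
    p <- sample(c(0, 1, 2), 1)
    out <- enrichment_score(r, set, p = p, return_curve = TRUE)
    expect_lt(abs(out$running_sum[n]), 1e-9)
    scaled <- ranked_fixture(r$score * 7.3, r$gene)
    expect_equal(enrichment_score(scaled, set, p = p)$es, out$es,
                 tolerance = 1e-12)
  }
})

test_that("ES agrees with the independent fgsea statistic (weighted form)", {
  set.seed(29)
  for (i in 1:50) {
    n <- sample(8:80, 1)
    sc <- sort(rnorm(n), decreasing = TRUE)
    r <- ranked_fixture(sc)
    set <- sample(r$gene, sample(2:(n - 2), 1))
    mine <- enrichment_score(r, set, p = 1)$es
    ref <- fgsea::calcGseaStat(stats::setNames(sc, r$gene),
                               selectedStats = sort(match(set, r$gene)),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("normalize_es is deterministic, sign-consistent and null-centered", {
  r <- ranked_fixture(sort(rnorm(40, sd = 2), decreasing = TRUE))
  set <- r$gene[c(1:4, 8)]
  a <- normalize_es(r, set, n_perm = 200, seed = 5)
  b <- normalize_es(r, set, n_perm = 200, seed = 5)
  expect_identical(a, b)
  expect_equal(sign(a$nes), sign(a$es))
  expect_true(a$p_value > 0 && a$p_value <= 1)
  expect_error(normalize_es(r, set, n_perm = 50), "100")
})

test_that("a strongly enriched top set gets NES > 1 and small p", {
  set.seed(37)
  sc <- sort(c(rnorm(10, 5, 0.5), rnorm(40, 0, 0.5)), decreasing = TRUE)
  r <- ranked_fixture(sc)
  out <- normalize_es(r, r$gene[1:8], n_perm = 500, seed = 2)
  expect_gt(out$nes, 1)
  expect_lt(out$p_value, 0.05)
})

test_that("run_gsea returns a tidy per-pathway table with BH adjustment", {
  coh <- generate_cohort(small_cohort_spec(n_patients = 15L, seed = 41L))
  panel <- small_panel()
  expr <- generate_expression(coh$samples, panel, seed = 42L)
  sets <- generate_gene_sets(panel, n_decoys = 5, seed = 43L)
  labels <- stats::setNames(coh$samples$ne_subtype, coh$samples$sample_id)[colnames(expr)]
  res <- run_gsea(expr, labels, sets, focal = "NE-low", n_perm = 200, seed = 3)
  expect_setequal(res$pathway, names(sets))
  expect_true(all(res$p_adj >= res$p_value))
  expect_equal(attr(res, "metric"), "signal_to_noise")
  expect_true(res[pathway == "immune_response", nes] > 0)
  expect_true(res[pathway == "cell_proliferation", nes] < 0)
})

test_that("nes_heatmap_matrix filters by max |NES| and z-scores with population sd", {
  results <- data.table(
    pathway = rep(c("p_signal", "p_flat", "p_weak"), each = 2),
    group = rep(c("g1", "g2"), 3),
    nes = c(2, -2, 1.4, 1.4, 0.5, -0.5))
  z <- nes_heatmap_matrix(results, threshold = 1)
  # population sd of (2, -2) is 2, so z is +/- 1
  expect_equal(unname(z["p_signal", ]), c(1, -1))
  # constant row survives the filter but z-scores to zero and is flagged
  expect_equal(unname(z["p_flat", ]), c(0, 0))
  expect_equal(attr(z, "flat_pathways"), "p_flat")
  # below-threshold pathway is dropped
  expect_false("p_weak" %in% rownames(z))
})
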