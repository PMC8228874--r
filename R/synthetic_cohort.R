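#' Specification of a synthetic SCLC cohort
#'
#' Defaults emulate the structure of a resected limited-stage SCLC cohort:
#' 32 patients, each contributing a primary tumor (two 1-mm cores, two
#' sections per core) and a matched lymph-node metastasis (one core, two
#' sections); neuroendocrine-high tumors form roughly two thirds of
#' primaries; matched metastases inherit the patient's NE label with a small
#' flip probability. Compartment density means come from the published
#' group means per marker, compartment, site and NE subtype (see
#' [default_density_means()]); densities are log-normal around those means
#' with a shared per-sample "infiltration" latent factor inducing the target
#' rank correlations, and counts are negative-binomial given density and a
#' log-normal measured area, so density estimates carry realistic integer
#' sampling noise.
#'
#' @param n_patients Number of patients (each yields a primary + LN sample).
#' @param ne_high_fraction Probability a primary tumor is NE-high.
#' @param markers Marker names counted in both compartments.
#' @param density_means data.table (`marker`, `compartment`, `site`, `ne`,
#'   `mean`) of mean densities in cells/mm^2.
#' @param density_dispersion Coefficient of variation of the within-group
#'   log-normal density distribution.
#' @param target_correlations data.table (`param_a`, `param_b`, `rho`) of
#'   pooled-cohort Spearman targets between parameters in the short
#'   `CD68t`/`CD163s` form, honored via a single latent factor (see
#'   [solve_factor_loadings()]).
#' @param ln_flip_prob Probability an LN metastasis flips the patient's NE
#'   label.
#' @param nb_size Negative-binomial size (dispersion) of counts given
#'   density x area.
#' @param area_mm2 Named mean measured area per compartment (mm^2).
#' @param seed Integer seed; all generation is deterministic given it.
#' @return A validated list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_patients = 32L,
                        ne_high_fraction = 20 / 31,
                        markers = c("CD68", "CD163", "CD33", "CD45", "CD3"),
                        density_means = default_density_means(),
                        density_dispersion = 0.8,
                        target_correlations = default_target_correlations(),
                        ln_flip_prob = 0.1,
                        nb_size = 20,
                        area_mm2 = c(stroma = 0.30, tumor_nest = 0.35),
                        seed = 1L) {
  stopifnot(n_patients >= 1, ne_high_fraction >= 0, ne_high_fraction <= 1,
            density_dispersion > 0, ln_flip_prob >= 0, ln_flip_prob <= 1,
            nb_size > 0, all(area_mm2 > 0))
  dm <- data.table::as.data.table(density_means)
  if (any(dm$mean < 0)) stop("density means must be non-negative")
  tc <- data.table::as.data.table(target_correlations)
  if (nrow(tc) && any(abs(tc$rho) > 1)) stop("correlation targets must lie in [-1, 1]")
  spec <- list(n_patients = as.integer(n_patients),
               ne_high_fraction = ne_high_fraction, markers = markers,
               density_means = dm, density_dispersion = density_dispersion,
               target_correlations = tc, ln_flip_prob = ln_flip_prob,
               nb_size = nb_size, area_mm2 = area_mm2, seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  # fail fast on unsatisfiable correlation structure
  spec$loadings <- solve_factor_loadings(spec)
  spec
}

#' Default compartment density means (cells/mm^2)
#'
#' Group means per marker, compartment, site and NE subtype. Macrophage and
#' myeloid means are the published cohort means; CD45/CD3 means (not
#' published as densities) are chosen once so that the tumor-nest immune
#' composition matches the published percentages (CD68+ cells are 64%/71%
#' and CD3+ cells 38%/18% of CD45+ cells in NE-low/NE-high primary nests).
#'
#' @return data.table with columns `marker`, `compartment`, `site`, `ne`,
#'   `mean`.
#' @export
default_density_means <- function() {
  build <- function(site, marker, stroma_low, stroma_high, tumor_low, tumor_high) {
    data.table::data.table(
      marker = marker,
      compartment = rep(c("stroma", "tumor_nest"), each = 2L),
      site = site,
      ne = rep(c("NE-low", "NE-high"), 2L),
      mean = c(stroma_low, stroma_high, tumor_low, tumor_high))
  }
  data.table::rbindlist(list(
    build("primary", "CD68", 625, 305, 101, 28),
    build("primary", "CD163", 523, 290, 54, 9),
    # CD33 is scored ordinally (published mean scores ~2.05 vs ~0.8 in the
    # primary stroma); the density means here are back-converted so the
    # generated ordinal scores reproduce those score means under the
    # 0.3 mm^2 stromal compartment and the score bins
    build("primary", "CD33", 65, 9, 1, 0.5),
    build("primary", "CD45", 1100, 700, 158, 39.4),
    build("primary", "CD3", 480, 300, 60, 7.1),
    build("ln", "CD68", 410, 614, 36, 76),
    build("ln", "CD163", 496, 410, 29, 46),
    build("ln", "CD33", 55, 10, 1, 0.5),
    build("ln", "CD45", 950, 900, 75, 120),
    build("ln", "CD3", 470, 420, 32, 45)))
}

#' Default pooled rank-correlation targets
#'
#' The subset of published pooled-cohort Spearman coefficients that a single
#' latent infiltration factor can honor simultaneously after accounting for
#' the NE-group mean component (the full published grid is overdetermined
#' for a one-factor model; see the methods vignette).
#'
#' @return data.table with columns `param_a`, `param_b`, `rho`.
#' @export
default_target_correlations <- function() {
  data.table::data.table(
    param_a = c("CD68t", "CD68s", "CD33s"),
    param_b = c("CD163t", "CD163s", "CD163s"),
    rho = c(0.76, 0.455, 0.651))
}

#' Solve single-factor loadings that realize pooled correlation targets
#'
#' Pooled Spearman targets are converted to normal-scale Pearson
#' correlations (`r = 2 sin(pi * rho / 6)`), the between-NE-group mean
#' component implied by the density means is subtracted, and the remaining
#' within-group correlation `r_w[i,j]` must factor as `l_i * l_j` for
#' per-parameter loadings on one latent factor. Loadings are solved by
#' minimum-norm least squares in log space; signs by 2-coloring the target
#' graph. Targets are rejected with a diagnostic when they are not
#' representable (|within correlation| > 1, a loading above 1 — the
#' one-factor analogue of a non-positive-semidefinite correlation matrix —
#' or an inconsistent sign cycle).
#'
#' @param spec A `cohort_spec` (the `loadings` field may be unset).
#' @param default_loading Loading for parameters not in any target.
#' @return Named numeric vector of loadings per parameter (`CD68s`, ...).
#' @export
solve_factor_loadings <- function(spec, default_loading = 0.5) {
  dm <- spec$density_means[site == "primary"]
  dm[, param := paste0(marker, ifelse(compartment == "stroma", "s", "t"))]
  params <- sort(unique(dm$param))
  f <- spec$ne_high_fraction
  sw2 <- log(1 + spec$density_dispersion^2)
  # log-scale NE-low minus NE-high mean gap per parameter
  delta <- vapply(params, function(p) {
    lo <- dm[param == p & ne == "NE-low", mean]
    hi <- dm[param == p & ne == "NE-high", mean]
    if (lo <= 0 || hi <= 0) 0 else log(lo) - log(hi)
  }, numeric(1))
  sb2 <- f * (1 - f) * delta^2
  st <- sqrt(sw2 + sb2)
  # counting noise attenuates observed correlations: approximate the
  # log-scale measurement variance of a replicate-averaged density estimate
  # (4 sections for a primary tumor) and compensate the targets for it
  mix_mean <- vapply(params, function(p) {
    m <- dm[param == p, mean]
    sum(m * c(1 - f, f)[match(dm[param == p, ne], c("NE-low", "NE-high"))])
  }, numeric(1))
  area <- spec$area_mm2[ifelse(grepl("s$", params), "stroma", "tumor_nest")]
  mu_count <- pmax(mix_mean * area, 1e-6)
  meas_var <- (1 / mu_count + 1 / spec$nb_size) / 4
  att <- sqrt((sw2 + sb2) / (sw2 + sb2 + meas_var))
  names(att) <- params
  loadings <- stats::setNames(rep(default_loading, length(params)), params)
  tc <- spec$target_correlations
  if (!nrow(tc)) return(loadings)
  bad <- setdiff(unique(c(tc$param_a, tc$param_b)), params)
  if (length(bad)) stop("correlation target references unknown parameter(s): ",
                        paste(bad, collapse = ", "))
  r_t <- 2 * sin(pi * tc$rho / 6) / (att[tc$param_a] * att[tc$param_b])
  if (any(abs(r_t) > 1)) {
    stop("unsatisfiable correlation target(s): measurement noise makes the ",
         "pooled target unreachable for pair(s) ",
         paste(tc$param_a[abs(r_t) > 1], tc$param_b[abs(r_t) > 1],
               sep = "~", collapse = ", "))
  }
  r_w <- (r_t * st[tc$param_a] * st[tc$param_b] -
            f * (1 - f) * delta[tc$param_a] * delta[tc$param_b]) / sw2
  if (any(abs(r_w) > 1)) {
    stop("unsatisfiable correlation target(s): required within-group ",
         "correlation outside [-1, 1] for pair(s) ",
         paste(tc$param_a[abs(r_w) > 1], tc$param_b[abs(r_w) > 1],
               sep = "~", collapse = ", "))
  }
  if (any(r_w == 0)) stop("correlation target implies exactly zero within-group ",
                          "correlation; remove the pair instead")
  # signs via 2-coloring of the target graph
  vs <- sort(unique(c(tc$param_a, tc$param_b)))
  sign_of <- stats::setNames(rep(NA_real_, length(vs)), vs)
  for (v in vs) {
    if (!is.na(sign_of[v])) next
    sign_of[v] <- 1
    queue <- v
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      hit <- which(tc$param_a == cur | tc$param_b == cur)
      for (e in hit) {
        other <- if (tc$param_a[e] == cur) tc$param_b[e] else tc$param_a[e]
        want <- sign_of[cur] * sign(r_w[e])
        if (is.na(sign_of[other])) {
          sign_of[other] <- want
          queue <- c(queue, other)
        } else if (sign_of[other] != want) {
          stop("unsatisfiable correlation targets: inconsistent sign cycle")
        }
      }
    }
  }
  # minimum-norm solution of A x = b with x = log|loading| <= 0; loadings
  # whose unconstrained solution exceeds 1 are clamped at 1 and the rest
  # re-solved, so a satisfiable chain is always found when one exists
  a_mat <- matrix(0, nrow(tc), length(vs), dimnames = list(NULL, vs))
  for (e in seq_len(nrow(tc))) {
    a_mat[e, tc$param_a[e]] <- 1
    a_mat[e, tc$param_b[e]] <- 1
  }
  b <- log(abs(r_w))
  x <- stats::setNames(rep(0, length(vs)), vs)
  free <- vs
  min_norm <- function(a, b) {
    sv <- svd(a)
    pos <- sv$d > max(sv$d) * 1e-10
    drop(sv$v[, pos, drop = FALSE] %*%
           ((crossprod(sv$u[, pos, drop = FALSE], b)) / sv$d[pos]))
  }
  repeat {
    if (!length(free)) break
    sol <- min_norm(a_mat[, free, drop = FALSE],
                    b - a_mat[, setdiff(vs, free), drop = FALSE] %*%
                      x[setdiff(vs, free)])
    x[free] <- sol
    over <- free[x[free] > 1e-10]
    if (!length(over)) break
    x[over] <- 0 # loading clamped at 1
    free <- setdiff(free, over)
  }
  resid <- drop(a_mat %*% x) - b
  if (max(abs(resid)) > 0.1) {
    stop("unsatisfiable correlation targets: not representable by a single ",
         "latent factor with loadings in [-1, 1] (max log-scale residual ",
         signif(max(abs(resid)), 2), "); the implied correlation matrix is ",
         "effectively not positive semi-definite")
  }
  if (max(abs(resid)) > 0.02) {
    warning("correlation targets are only approximately one-factor ",
            "representable; realized correlations are a least-squares ",
            "compromise (max log-scale residual ",
            signif(max(abs(resid)), 2), ")")
  }
  loadings[vs] <- exp(x) * sign_of[vs]
  loadings
}

#' Generate a synthetic cohort: sample table and compartment counts
#'
#' @param spec A [cohort_spec()].
#' @return List with `samples` (sample_id, patient_id, site, ne_subtype,
#'   latent_infiltration) and `counts` (the per-core, per-section
#'   compartment count table consumed by [average_replicates()]).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n <- spec$n_patients
  patient_id <- sprintf("P%04d", seq_len(n))
  ne_primary <- ifelse(stats::runif(n) < spec$ne_high_fraction, "NE-high", "NE-low")
  flip <- stats::runif(n) < spec$ln_flip_prob
  ne_ln <- ifelse(flip, ifelse(ne_primary == "NE-high", "NE-low", "NE-high"),
                  ne_primary)
  z_patient <- stats::rnorm(n)
  samples <- data.table::data.table(
    sample_id = c(paste0(patient_id, "_PRI"), paste0(patient_id, "_LN")),
    patient_id = rep(patient_id, 2L),
    site = rep(c("primary", "ln"), each = n),
    ne_subtype = c(ne_primary, ne_ln))
  # per-sample infiltration factor, correlated within a patient
  samples[, latent_infiltration :=
            sqrt(0.5) * rep(z_patient, 2L) + sqrt(0.5) * stats::rnorm(2L * n)]

  dm <- data.table::copy(spec$density_means)
  dm[, param := paste0(marker, ifelse(compartment == "stroma", "s", "t"))]
  loadings <- spec$loadings
  sw <- sqrt(log(1 + spec$density_dispersion^2))
  grid <- dm[, .(marker, compartment, site, ne, mean, param)]
  series <- samples[, .(sample_id, site, ne = ne_subtype, z = latent_infiltration)]
  dens <- merge(series, grid, by.x = c("site", "ne"), by.y = c("site", "ne"),
                allow.cartesian = TRUE)
  l <- loadings[dens$param]
  l[is.na(l)] <- 0.5
  u <- l * dens$z + sqrt(1 - l^2) * stats::rnorm(nrow(dens))
  dens[, density := ifelse(mean <= 0, 0, exp(log(mean) - sw^2 / 2 + sw * u))]

  layout <- data.table::rbindlist(list(
    data.table::CJ(site = "primary", core_id = c("A", "B"), section_id = c("S1", "S2")),
    data.table::CJ(site = "ln", core_id = "A", section_id = c("S1", "S2"))))
  counts <- merge(dens[, .(sample_id, site, marker, compartment, density)],
                  layout, by = "site", allow.cartesian = TRUE)
  area_mean <- spec$area_mm2[counts$compartment]
  sdlog <- 0.25
  area_mm2 <- stats::rlnorm(nrow(counts), log(area_mean) - sdlog^2 / 2, sdlog)
  counts[, area_um2 := area_mm2 * 1e6]
  counts[, cell_count := stats::rnbinom(.N, mu = density * area_mm2,
                                        size = spec$nb_size)]
  counts <- counts[, .(sample_id, core_id, section_id, marker, compartment,
                       cell_count, area_um2)]
  data.table::setorder(counts, sample_id, marker, compartment, core_id, section_id)
  data.table::setorder(samples, site, sample_id)
  list(samples = samples[], counts = counts[])
}

#' Specification of a synthetic targeted expression panel
#'
#' Partitions `n_genes` panel genes into immune-response, proliferation and
#' neuroendocrine modules plus background. Immune genes are shifted up by
#' `effect_size` log2 units in NE-low samples (plus a small coupling to the
#' sample's infiltration factor); proliferation and neuroendocrine genes are
#' shifted up in NE-high samples. A per-gene calibration table can pin
#' individual genes' group means to published values (see
#' [default_calibrated_genes()]); calibrated genes override the module
#' shift.
#'
#' @param n_genes Total panel size (default 2560).
#' @param module_sizes Named integer vector for `immune`, `proliferation`,
#'   `neuroendocrine` module sizes (each includes its named marker genes).
#' @param effect_size Log2 shift applied to module genes in the favored
#'   phenotype.
#' @param noise_sd Per-gene, per-sample residual sd (log2 units).
#' @param patient_sd Sd of the patient-level random effect shared by a
#'   patient's primary and LN sample.
#' @param infiltration_coef Coupling of immune-module genes to the sample's
#'   latent infiltration factor (log2 units per factor sd); the default
#'   makes bulk immune-gene expression track the immune infiltrate, so
#'   infiltration-phenotype contrasts carry signal beyond the NE label.
#' @param baseline_mean,baseline_sd Distribution of per-gene baseline log2
#'   expression.
#' @param calibrated Optional data.table (`gene`, `mean_ne_low`,
#'   `mean_ne_high`) pinning per-gene group means; NULL disables.
#' @return List of class `"panel_spec"` with a `genes` table (`gene`,
#'   `module`).
#' @export
panel_spec <- function(n_genes = 2560L,
                       module_sizes = c(immune = 120L, proliferation = 100L,
                                        neuroendocrine = 40L),
                       effect_size = 1.5,
                       noise_sd = 1.0,
                       patient_sd = 0.6,
                       infiltration_coef = 0.8,
                       baseline_mean = 6,
                       baseline_sd = 1.2,
                       calibrated = default_calibrated_genes()) {
  stopifnot(n_genes >= sum(module_sizes), noise_sd > 0, patient_sd >= 0,
            all(module_sizes >= 0))
  named <- list(
    immune = c("CSF1", "CXCR2", "IL4R", "VEGFC", "CXCL9", "CXCL10", "GZMA",
               "CD70", "CD27", "FCGR1A", "HLA-B", "TAP1", "CD74", "ITGAM",
               "IFI27", "BIRC3", "REL", "TNFSF10", "CD44", "ANXA1", "ITGB6",
               "MMP7", "KRT5", "TP63", "YBX3", "CXCR3"),
    proliferation = c("MKI67", "CCNB1", "CDK1", "TOP2A", "BUB1", "PLK1",
                      "AURKA", "AURKB", "E2F1", "FOXM1", "CCNA2", "CDC20"),
    neuroendocrine = c("ASCL1", "NEUROD1", "GRP", "ISL1", "CHGA", "CDH2",
                       "SYP", "NCAM1", "SOX3", "INS", "FGF5", "DLL3",
                       "FOXA2", "L1CAM", "TP73", "DNAJC6"))
  stem <- c(immune = "IMM", proliferation = "PRO", neuroendocrine = "NEU")
  genes <- list()
  for (mod in names(module_sizes)) {
    base <- named[[mod]]
    extra <- module_sizes[[mod]] - length(base)
    if (extra < 0) stop("module_sizes[", mod, "] smaller than its named genes")
    genes[[mod]] <- data.table::data.table(
      gene = c(base, sprintf("%s%04d", stem[[mod]], seq_len(extra))),
      module = mod)
  }
  n_bg <- n_genes - sum(module_sizes)
  genes$background <- data.table::data.table(
    gene = sprintf("GENE%04d", seq_len(n_bg)), module = "background")
  gene_table <- data.table::rbindlist(genes)
  stopifnot(!anyDuplicated(gene_table$gene))
  if (!is.null(calibrated)) {
    calibrated <- data.table::as.data.table(calibrated)
    miss <- setdiff(calibrated$gene, gene_table$gene)
    if (length(miss)) stop("calibrated gene(s) not in panel: ",
                           paste(miss, collapse = ", "))
  }
  structure(list(n_genes = as.integer(n_genes), genes = gene_table,
                 module_sizes = module_sizes, effect_size = effect_size,
                 noise_sd = noise_sd, patient_sd = patient_sd,
                 infiltration_coef = infiltration_coef,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 calibrated = calibrated),
            class = "panel_spec")
}

#' Published per-gene group means used to calibrate the generator
#'
#' Log2-scale panel group means (NE-low, NE-high) for four immune/stromal
#' signaling genes, taken from the source cohort's printed values. They pin
#' these genes' generated group means so that pipeline group-mean summaries
#' are comparable with the published ones.
#'
#' @return data.table with `gene`, `mean_ne_low`, `mean_ne_high`.
#' @export
default_calibrated_genes <- function() {
  data.table::data.table(
    gene = c("CSF1", "VEGFC", "IL4R", "CXCR2"),
    mean_ne_low = c(7.23, 7.59, 8.71, 5.5),
    mean_ne_high = c(5.91, 5.95, 7.88, 3.83))
}

#' Generate a synthetic log2 expression matrix for a cohort
#'
#' @param samples Sample table from [generate_cohort()] (needs `sample_id`,
#'   `patient_id`, `ne_subtype`, `latent_infiltration`).
#' @param panel A [panel_spec()].
#' @param seed Integer seed.
#' @return Numeric matrix, genes x samples, log2 scale, with the panel gene
#'   table in `attr(, "modules")`.
#' @export
generate_expression <- function(samples, panel, seed = 1L) {
  stopifnot(inherits(panel, "panel_spec"))
  samples <- data.table::as.data.table(samples)
  if (!"ne_subtype" %in% names(samples)) stop("samples need an ne_subtype column")
  withr_seed(seed, generate_expression_impl(samples, panel))
}

generate_expression_impl <- function(samples, panel) {
  genes <- panel$genes
  ng <- nrow(genes)
  ns <- nrow(samples)
  baseline <- stats::rnorm(ng, panel$baseline_mean, panel$baseline_sd)
  names(baseline) <- genes$gene
  # per-gene means by NE group: module shifts, then calibration overrides
  mu_low <- baseline
  mu_high <- baseline
  eff <- panel$effect_size
  mu_low[genes$module == "immune"] <- mu_low[genes$module == "immune"] + eff
  mu_high[genes$module %in% c("proliferation", "neuroendocrine")] <-
    mu_high[genes$module %in% c("proliferation", "neuroendocrine")] + eff
  if (!is.null(panel$calibrated)) {
    idx <- match(panel$calibrated$gene, genes$gene)
    mu_low[idx] <- panel$calibrated$mean_ne_low
    mu_high[idx] <- panel$calibrated$mean_ne_high
  }
  patients <- unique(samples$patient_id)
  b_pat <- stats::setNames(stats::rnorm(length(patients), 0, panel$patient_sd),
                           patients)
  is_low <- samples$ne_subtype == "NE-low"
  mu <- matrix(0, ng, ns)
  mu[, is_low] <- mu_low
  mu[, !is_low] <- mu_high
  expr <- mu + stats::rnorm(ng * ns, 0, panel$noise_sd)
  expr <- sweep(expr, 2L, b_pat[samples$patient_id], `+`)
  if (panel$infiltration_coef != 0 && "latent_infiltration" %in% names(samples)) {
    imm <- genes$module == "immune"
    expr[imm, ] <- expr[imm, , drop = FALSE] +
      rep(panel$infiltration_coef * samples$latent_infiltration, each = sum(imm))
  }
  dimnames(expr) <- list(genes$gene, samples$sample_id)
  attr(expr, "modules") <- genes
  expr
}

#' Gene-set collection for a synthetic panel
#'
#' One gene set per expression module plus random decoy sets drawn from the
#' whole panel, mimicking a flat pathway collection.
#'
#' @param panel A [panel_spec()].
#' @param n_decoys Number of random decoy sets.
#' @param decoy_size Genes per decoy set.
#' @param seed Integer seed for the decoy draw.
#' @return Named list of character vectors.
#' @export
generate_gene_sets <- function(panel, n_decoys = 20L, decoy_size = 40L,
                               seed = 1L) {
  stopifnot(inherits(panel, "panel_spec"))
  genes <- panel$genes
  sets <- list(
    immune_response = genes[module == "immune", gene],
    cell_proliferation = genes[module == "proliferation", gene],
    neuroendocrine_differentiation = genes[module == "neuroendocrine", gene])
  decoys <- withr_seed(seed, {
    lapply(seq_len(n_decoys), function(i) sample(genes$gene, decoy_size))
  })
  names(decoys) <- sprintf("decoy_%03d", seq_len(n_decoys))
  c(sets, decoys)
}

#' Random interaction edge table with module structure
#'
#' Gene pairs within the same expression module are connected with
#' `within_boost` times the baseline probability of across-module pairs, so
#' module-driven target lists yield denser induced networks than random
#' selections. Scores are uniform on (0.4, 1].
#'
#' @param panel A [panel_spec()].
#' @param density Baseline (across-module) edge probability in `[0, 1]`.
#'   The default, with the default boost, makes a module-driven target
#'   selection about as interconnected as published string maps of
#'   co-functional gene sets (edge-to-node ratios near 2).
#' @param seed Integer seed.
#' @param within_boost Multiplier on `density` for within-module pairs
#'   (capped at probability 1).
#' @return data.table with `gene_a`, `gene_b`, `score`, deduplicated and
#'   lexicographically ordered endpoints.
#' @export
generate_interactions <- function(panel, density = 0.006, seed = 1L,
                                  within_boost = 8) {
  stopifnot(inherits(panel, "panel_spec"), density >= 0, density <= 1,
            within_boost >= 0)
  if (density == 0) {
    return(data.table::data.table(gene_a = character(), gene_b = character(),
                                  score = numeric()))
  }
  withr_seed(seed, generate_interactions_impl(panel, density, within_boost))
}

generate_interactions_impl <- function(panel, density, within_boost) {
  genes <- panel$genes
  modules <- setdiff(unique(genes$module), "background")
  p_within <- min(1, density * within_boost)
  within <- list()
  for (mod in modules) {
    g <- genes[module == mod, gene]
    if (length(g) < 2L) next
    pairs <- utils::combn(sort(g), 2L)
    keep <- stats::runif(ncol(pairs)) < p_within
    within[[mod]] <- data.table::data.table(gene_a = pairs[1, keep],
                                            gene_b = pairs[2, keep])
  }
  within <- data.table::rbindlist(within)
  if (!nrow(within)) {
    within <- data.table::data.table(gene_a = character(), gene_b = character())
  }
  # across-module edges: Bernoulli(density) over the remaining pairs,
  # realized by sampling the expected binomial count of distinct pairs
  all_genes <- sort(genes$gene)
  ng <- length(all_genes)
  n_pairs <- ng * (ng - 1) / 2
  mod_of <- stats::setNames(genes$module, genes$gene)
  n_within_pairs <- sum(vapply(modules, function(m) {
    k <- sum(genes$module == m); k * (k - 1) / 2
  }, numeric(1)))
  m <- stats::rbinom(1L, as.integer(n_pairs - n_within_pairs), density)
  across <- data.table::data.table(gene_a = character(), gene_b = character())
  while (nrow(across) < m) {
    need <- m - nrow(across)
    i <- sample.int(ng, 2L * need + 10L, replace = TRUE)
    j <- sample.int(ng, 2L * need + 10L, replace = TRUE)
    ok <- i != j
    a <- pmin(i[ok], j[ok]); b <- pmax(i[ok], j[ok])
    cand <- unique(data.table::data.table(gene_a = all_genes[a],
                                          gene_b = all_genes[b]))
    same_mod <- mod_of[cand$gene_a] == mod_of[cand$gene_b] &
      mod_of[cand$gene_a] != "background"
    cand <- cand[!same_mod]
    across <- unique(data.table::rbindlist(list(across, cand)))
  }
  across <- across[seq_len(m)]
  edges <- unique(data.table::rbindlist(list(within, across)))
  edges[, score := 1 - 0.6 * stats::runif(.N)] # uniform on (0.4, 1]
  data.table::setorder(edges, gene_a, gene_b)
  edges[]
}
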