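#' Default pipeline configuration
#'
#' All tunables of the end-to-end analysis in one list. Any element can be
#' overridden via the `...` of [run_pipeline()].
#'
#' @param seed Master seed; every stochastic stage derives its own stream
#'   from it, so reruns are byte-identical.
#' @return Named list.
#' @export
pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    mad_c = 0,                     # MAD multiplier for dichotomization
    cutoff_samples = NULL,         # NULL = cutoffs on all samples pooled
    composition_mode = "ratio_of_sums",
    correlation_method = "spearman",
    gsea = list(metric = "signal_to_noise", p = 1, n_perm = 1000L,
                min_size = 3L),
    de = list(shrink = 0, var_floor = 0.05, p_for_category = "p_adj"),
    volcano = list(lfc_strong = 2, lfc_moderate = 1.5, alpha = 0.05),
    network = list(min_score = 0.4, p_col = "p_adj", alpha = 0.05,
                   lfc_min = 1.5, edges_per_node = "ratio"),
    macrophage_params = c("CD68s", "CD68t", "CD163s", "CD163t", "CD33s",
                          "MHCIIt"))
}

#' Run the full compartment-resolved TME analysis
#'
#' Orchestrates the stages on one input bundle: replicate-averaged
#' densities and ordinal scores, MAD dichotomization, immune-oasis/-desert
#' and macrophage phenotypes, the rank-correlation grid, per-group
#' preranked GSEA with the z-scored pathway matrix, differential expression
#' for the NE and phenotype contrasts with volcano categories, and the
#' connectivity statistics of the induced interaction networks.
#'
#' @param data List with elements `samples` (sample table with `sample_id`,
#'   `site`, `ne_subtype`), `counts` (compartment count table),
#'   `expression` (genes x samples log2 matrix), `gene_sets` (named list),
#'   `edges` (interaction edge table). File paths are accepted for
#'   `counts`/`expression`/`gene_sets`/`edges` and read with the package
#'   readers.
#' @param config List from [pipeline_config()]; individual elements may be
#'   overridden via `...`.
#' @param ... Scalar overrides of top-level config elements.
#' @return Named list of result tables plus `meta` (seed, config, package
#'   version).
#' @export
run_pipeline <- function(data, config = pipeline_config(), ...) {
  dots <- list(...)
  config[names(dots)] <- dots
  samples <- data.table::as.data.table(data$samples)
  counts <- if (is.character(data$counts)) read_counts(data$counts)
            else as_count_table(data$counts)
  expr <- if (is.character(data$expression)) read_expression(data$expression)
          else data$expression
  gene_sets <- if (is.character(data$gene_sets)) read_gmt(data$gene_sets)
               else data$gene_sets
  edges <- if (is.character(data$edges)) read_edges(data$edges)
           else as_interaction_edges(data$edges)

  check_sample_ids(samples, counts, expr)
  ne <- stats::setNames(samples$ne_subtype, samples$sample_id)
  primary_ids <- samples[site == "primary", sample_id]

  ## morphometry: CD33 stays ordinal, everything else becomes a density
  densities <- average_replicates(counts[marker != "CD33"])
  cd33 <- cd33_scores(counts[marker == "CD33"])
  comp <- data.table::rbindlist(lapply(c("primary", "ln"), function(st) {
    ids <- samples[site == st, sample_id]
    if (!length(ids)) return(NULL)
    out <- composition(densities[sample_id %in% ids], groups = ne,
                       mode = config$composition_mode)
    out[, site := st]
    out
  }))

  ## dichotomization and phenotypes
  ann <- annotate_markers(densities, scores = cd33, c = config$mad_c,
                          samples = config$cutoff_samples)
  phenotypes <- classify_immune_phenotype(ann$annotation)
  mac <- macrophage_class(ann$annotation,
                          params = config$macrophage_params)

  ## association stage (correlations on primary tumors, as published)
  correlations <- correlation_matrix(densities,
                                     method = config$correlation_method,
                                     samples = primary_ids)

  ## per-group preranked GSEA: NE phenotype plus each biomarker's HIGH group
  gsea_groups <- list("NE-low" = ne == "NE-low", "NE-high" = ne == "NE-high")
  ann_wide <- ann$annotation
  for (param in setdiff(names(ann_wide), "sample_id")) {
    calls <- stats::setNames(ann_wide[[param]], ann_wide$sample_id)
    gsea_groups[[param]] <- calls == "HIGH"
  }
  enrichment <- list()
  sample_order <- colnames(expr)
  for (i in seq_along(gsea_groups)) {
    gname <- names(gsea_groups)[i]
    ind <- gsea_groups[[i]][sample_order]
    labels <- ifelse(ind, "focal", "rest")
    if (sum(labels == "focal", na.rm = TRUE) < 2L ||
        sum(labels == "rest", na.rm = TRUE) < 2L) next
    enrichment[[gname]] <- run_gsea(
      expr, labels, gene_sets, group = gname,
      metric = config$gsea$metric, focal = "focal", p = config$gsea$p,
      n_perm = config$gsea$n_perm, seed = config$seed + 1000L * i,
      min_size = config$gsea$min_size)
  }
  enrichment <- data.table::rbindlist(enrichment)
  nes_matrix <- nes_heatmap_matrix(enrichment)

  ## differential expression + networks for the two headline contrasts
  phen <- stats::setNames(phenotypes$phenotype, phenotypes$sample_id)
  contrasts <- list(
    ne = list(labels = ne[sample_order], focal = "NE-low"),
    phenotype = list(labels = ifelse(phen[sample_order] %in% c("oasis", "desert"),
                                     phen[sample_order], NA),
                     focal = "oasis"))
  de <- list(); networks <- list(); net_stats <- list()
  for (nm in names(contrasts)) {
    ctr <- contrasts[[nm]]
    res <- de_test(expr, ctr$labels, focal = ctr$focal,
                   shrink = config$de$shrink, var_floor = config$de$var_floor,
                   p_for_category = config$de$p_for_category)
    de[[nm]] <- res
    for (side in c("up", "down")) {
      sel <- if (side == "up") res else data.table::copy(res)[, log2fc := -log2fc]
      nodes <- select_nodes(sel, p_col = config$network$p_col,
                            alpha = config$network$alpha,
                            lfc_min = config$network$lfc_min)
      g <- build_network(nodes, edges, min_score = config$network$min_score)
      key <- paste(nm, side, sep = "_")
      networks[[key]] <- g
      net_stats[[key]] <- connectivity_stats(
        g, edges_per_node = config$network$edges_per_node)
    }
  }
  overlap_up <- target_overlap(
    select_nodes(de$ne, p_col = config$network$p_col,
                 alpha = config$network$alpha, lfc_min = config$network$lfc_min),
    select_nodes(de$phenotype, p_col = config$network$p_col,
                 alpha = config$network$alpha, lfc_min = config$network$lfc_min))

  meta <- list(seed = config$seed, config = config,
               package_version = as.character(utils::packageVersion("sclcTME")),
               n_samples = nrow(samples), n_genes = nrow(expr))
  list(densities = densities, cd33_scores = cd33, composition = comp,
       cutoffs = ann$cutoffs, annotation = ann$annotation,
       phenotypes = phenotypes, macrophage = mac,
       correlations = correlations, enrichment = enrichment,
       nes_matrix = nes_matrix, de = de, networks = networks,
       network_stats = net_stats, overlap_up = overlap_up, meta = meta)
}

#' Ordinal CD33-style scores from raw counts
#'
#' Section counts are averaged within a core, core means averaged per
#' sample, and the rounded mean count is binned with [cd33_score()].
#'
#' @param counts Count table restricted to the ordinal marker.
#' @return data.table `sample_id`, `marker`, `compartment`, `score`.
#' @export
cd33_scores <- function(counts) {
  dt <- as_count_table(counts)
  core <- dt[, .(cell_count = mean(cell_count)),
             by = .(sample_id, marker, compartment, core_id)]
  out <- core[, .(mean_count = mean(cell_count)),
              by = .(sample_id, marker, compartment)]
  out[, score := cd33_score(round(mean_count))]
  out[, mean_count := NULL]
  out[]
}

check_sample_ids <- function(samples, counts, expr) {
  known <- samples$sample_id
  bad_counts <- setdiff(unique(counts$sample_id), known)
  bad_expr <- setdiff(colnames(expr), known)
  if (length(bad_counts) || length(bad_expr)) {
    stop("sample ID mismatch: ",
         if (length(bad_counts)) paste0("count table has unknown ids [",
           paste(utils::head(bad_counts, 5L), collapse = ", "), "] "),
         if (length(bad_expr)) paste0("expression matrix has unknown ids [",
           paste(utils::head(bad_expr, 5L), collapse = ", "), "]"))
  }
  invisible(TRUE)
}

#' Write the pipeline result bundle as TSV/JSON files
#'
#' @param result List from [run_pipeline()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the output directory.
#' @export
write_pipeline_results <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) data.table::fwrite(x, file.path(out_dir, name), sep = "\t")
  tsv(result$densities, "densities.tsv")
  tsv(result$cd33_scores, "cd33_scores.tsv")
  tsv(result$composition, "composition.tsv")
  tsv(result$cutoffs, "cutoffs.tsv")
  tsv(result$annotation, "annotation.tsv")
  tsv(result$phenotypes, "phenotypes.tsv")
  tsv(result$macrophage, "macrophage_class.tsv")
  tsv(result$correlations$long, "correlations.tsv")
  tsv(result$enrichment, "enrichment.tsv")
  utils::write.table(result$nes_matrix,
                     file.path(out_dir, "nes_heatmap_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  for (nm in names(result$de)) tsv(result$de[[nm]], paste0("de_", nm, ".tsv"))
  jsonlite::write_json(
    c(lapply(result$network_stats, function(s) s[c("n_nodes", "n_edges",
        "edges_per_node", "total_connection_score")]),
      list(overlap_up = result$overlap_up)),
    file.path(out_dir, "network_stats.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(seed = result$meta$seed,
         package_version = result$meta$package_version,
         n_samples = result$meta$n_samples, n_genes = result$meta$n_genes),
    file.path(out_dir, "run_meta.json"), auto_unbox = TRUE)
  invisible(out_dir)
}
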