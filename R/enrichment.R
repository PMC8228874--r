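#' Rank panel genes for a two-group contrast
#'
#' Produces the descending ranked list feeding the preranked enrichment
#' statistic. Positive scores mean higher expression in the focal group.
#' The default metric is signal-to-noise with the conventional standard
#' deviation floor (each group's sd is floored at 0.2 x |group mean|, and at
#' 0.2 when both are zero), which caps zero-variance genes at a finite score.
#' Ties are broken by gene identifier (lexicographic) so the order is
#' strictly deterministic.
#'
#' @param expr Numeric matrix, genes x samples (log2 scale), with rownames.
#' @param labels Character/factor vector over columns of `expr` giving the
#'   two groups; samples with NA labels are dropped.
#' @param focal Focal group label; defaults to the first factor level.
#' @param metric `"signal_to_noise"`, `"t_stat"` or `"log2fc"`.
#' @return data.table (`gene`, `score`) sorted by descending score, with the
#'   metric recorded in `attr(, "metric")` and the focal group in
#'   `attr(, "focal")`.
#' @export
rank_genes <- function(expr, labels,
                       metric = c("signal_to_noise", "t_stat", "log2fc"),
                       focal = NULL) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  labels <- as.factor(labels)
  keep <- !is.na(labels)
  expr <- expr[, keep, drop = FALSE]
  labels <- droplevels(labels[keep])
  if (nlevels(labels) != 2L) stop("labels must define exactly two groups")
  if (is.null(focal)) focal <- levels(labels)[1]
  if (!focal %in% levels(labels)) stop("focal group not found in labels")
  g1 <- expr[, labels == focal, drop = FALSE]
  g2 <- expr[, labels != focal, drop = FALSE]
  if (ncol(g1) < 2L || ncol(g2) < 2L) stop("each group needs at least 2 samples")
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  score <- switch(metric,
    log2fc = m1 - m2,
    signal_to_noise = {
      s1 <- apply(g1, 1L, stats::sd); s2 <- apply(g2, 1L, stats::sd)
      s1 <- pmax(s1, 0.2 * abs(m1)); s1[s1 == 0] <- 0.2
      s2 <- pmax(s2, 0.2 * abs(m2)); s2[s2 == 0] <- 0.2
      (m1 - m2) / (s1 + s2)
    },
    t_stat = {
      v1 <- apply(g1, 1L, stats::var) / ncol(g1)
      v2 <- apply(g2, 1L, stats::var) / ncol(g2)
      se <- sqrt(v1 + v2)
      se[se == 0] <- 0.2 # zero-variance floor keeps the statistic finite
      (m1 - m2) / se
    })
  out <- data.table::data.table(gene = rownames(expr), score = score)
  data.table::setorder(out, -score, gene)
  data.table::setattr(out, "metric", metric)
  data.table::setattr(out, "focal", focal)
  out[]
}

#' Weighted Kolmogorov-Smirnov running-sum enrichment score
#'
#' Walks the ranked list: positions in the gene set increment the running
#' sum by `|score|^p / sum_hits |score|^p`, positions outside decrement it by
#' `1 / (N - N_hits)`. The enrichment score is the running-sum value of
#' maximal absolute deviation from zero (ties between an equal positive and
#' negative deviation resolve to the positive one). The sum always returns
#' to zero at the end of the list.
#'
#' @param ranked Ranked list from [rank_genes()] (or any data.frame with
#'   `gene`, `score` in descending order).
#' @param gene_set Character vector of member genes.
#' @param p Weight exponent, `p >= 0`; `p = 0` is the classical unweighted
#'   KS statistic, `p = 1` the conventional weighted form.
#' @param return_curve Also return the full running-sum vector (length N).
#' @return List with `es`, `leading_edge` (genes at or before the extremum,
#'   in rank order for positive ES; at or after it for negative ES),
#'   `n_hits`, and `running_sum` when requested.
#' @export
enrichment_score <- function(ranked, gene_set, p = 1, return_curve = FALSE) {
  stopifnot(p >= 0)
  genes <- ranked$gene
  scores <- ranked$score
  n <- length(genes)
  pos <- sort(match(unique(gene_set), genes))
  pos <- pos[!is.na(pos)]
  k <- length(pos)
  if (k == 0L) stop("gene set is disjoint from the ranked universe")
  if (k == n) stop("gene set equals the ranked universe; misses undefined")
  w <- abs(scores[pos])^p
  tot <- sum(w)
  if (tot == 0) w[] <- 1 / k else w <- w / tot # all-zero hit scores: fall back to equal weights
  miss <- 1 / (n - k)
  cum_hit <- cumsum(w)
  # Running sum immediately after each hit, and just before each hit: the
  # extrema of the full curve can only occur at these 2k positions.
  after <- cum_hit - (pos - seq_len(k)) * miss
  before <- c(0, cum_hit[-k]) - (pos - seq_len(k)) * miss
  es_pos <- max(after)
  es_neg <- min(c(before, 0))
  es <- if (es_pos >= -es_neg) es_pos else es_neg
  if (es >= 0) {
    peak <- pos[which.max(after)]
    le <- genes[pos[pos <= peak]]
  } else {
    trough <- pos[which.min(before)]
    le <- genes[pos[pos >= trough]]
  }
  out <- list(es = es, leading_edge = le, n_hits = k)
  if (return_curve) {
    steps <- rep(-miss, n)
    steps[pos] <- w
    out$running_sum <- cumsum(steps)
  }
  out
}

# ES only, from precomputed |score|^p weights and hit positions; used by the
# permutation null where allocating the full result is wasteful.
es_from_positions <- function(wp, n, pos) {
  k <- length(pos)
  w <- wp[pos]
  tot <- sum(w)
  if (tot == 0) w <- rep(1 / k, k) else w <- w / tot
  miss <- 1 / (n - k)
  cum_hit <- cumsum(w)
  drift <- (pos - seq_len(k)) * miss
  after <- cum_hit - drift
  before <- c(0, cum_hit[-k]) - drift
  es_pos <- max(after)
  es_neg <- min(c(before, 0))
  if (es_pos >= -es_neg) es_pos else es_neg
}

#' Normalize an enrichment score against a gene-label permutation null
#'
#' Resamples `|set|` genes uniformly without replacement from the ranked
#' universe `n_perm` times. NES is the observed ES divided by the mean |ES|
#' of null draws with the same sign; the nominal p is the fraction of
#' same-sign null ES at least as extreme, with a +1 pseudocount in numerator
#' and denominator. If no null draw shares the sign, p is `1/(n_perm + 1)`
#' and the NES (normalized against all draws) is flagged unstable.
#'
#' @inheritParams enrichment_score
#' @param n_perm Number of permutations (at least 100).
#' @param seed Integer seed; the permutation stream is local to this call.
#' @return List with `es`, `nes`, `p_value`, `n_perm`, `unstable`,
#'   `leading_edge_size`.
#' @export
normalize_es <- function(ranked, gene_set, p = 1, n_perm = 1000L, seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  obs <- enrichment_score(ranked, gene_set, p = p)
  n <- nrow(ranked)
  k <- obs$n_hits
  wp <- abs(ranked$score)^p
  null_es <- withr_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) es_from_positions(wp, n, sort(sample.int(n, k))),
           numeric(1))
  })
  es <- obs$es
  if (es == 0) {
    return(list(es = 0, nes = 0, p_value = 1, n_perm = n_perm,
                unstable = FALSE, leading_edge_size = length(obs$leading_edge)))
  }
  same <- null_es[sign(null_es) == sign(es)]
  if (length(same) == 0L) {
    nes <- es / mean(abs(null_es))
    pval <- 1 / (n_perm + 1)
    unstable <- TRUE
  } else {
    nes <- es / mean(abs(same))
    pval <- (1 + sum(abs(same) >= abs(es))) / (length(same) + 1)
    unstable <- FALSE
  }
  list(es = es, nes = nes, p_value = pval, n_perm = n_perm,
       unstable = unstable, leading_edge_size = length(obs$leading_edge))
}

# Evaluate expr with a temporary RNG state seeded at `seed`, restoring the
# caller's state afterwards so pipeline stages do not perturb each other.
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Preranked GSEA of a gene-set collection for one contrast
#'
#' @param expr Genes x samples log2 expression matrix.
#' @param labels Two-group assignment over columns (NA drops a sample).
#' @param gene_sets Named list of character vectors.
#' @param group Label stored in the `group` column of the result (defaults
#'   to the focal group).
#' @param min_size,max_size Gene sets with fewer/more members present in the
#'   universe are skipped.
#' @inheritParams rank_genes
#' @inheritParams normalize_es
#' @return data.table: `pathway`, `group`, `es`, `nes`, `p_value`, `p_adj`
#'   (Benjamini-Hochberg across pathways), `size`, `leading_edge_size`,
#'   `unstable`; ranking metric and permutation count in attributes.
#' @export
run_gsea <- function(expr, labels, gene_sets, group = NULL,
                     metric = "signal_to_noise", focal = NULL,
                     p = 1, n_perm = 1000L, seed = 1L,
                     min_size = 3L, max_size = Inf) {
  ranked <- rank_genes(expr, labels, metric = metric, focal = focal)
  if (is.null(group)) group <- attr(ranked, "focal")
  rows <- list()
  for (i in seq_along(gene_sets)) {
    nm <- names(gene_sets)[i]
    members <- intersect(gene_sets[[i]], ranked$gene)
    if (length(members) < min_size || length(members) > max_size ||
        length(members) == nrow(ranked)) next
    r <- normalize_es(ranked, members, p = p, n_perm = n_perm,
                      seed = seed + i)
    rows[[nm]] <- data.table::data.table(
      pathway = nm, group = group, es = r$es, nes = r$nes,
      p_value = r$p_value, size = length(members),
      leading_edge_size = r$leading_edge_size, unstable = r$unstable)
  }
  out <- data.table::rbindlist(rows)
  if (nrow(out)) out[, p_adj := stats::p.adjust(p_value, "BH")]
  data.table::setcolorder(out, c("pathway", "group", "es", "nes",
                                 "p_value", "p_adj"))
  data.table::setattr(out, "metric", attr(ranked, "metric"))
  data.table::setattr(out, "n_perm", n_perm)
  out[]
}

#' Pathway-by-group matrix of z-scored NES for heatmap display
#'
#' Keeps pathways whose largest |NES| across groups exceeds `threshold`
#' (default 1, the usual display filter), then z-scores each pathway across
#' groups with the population (n) standard deviation — a display scaling,
#' not an inferential one. Pathways constant across groups get a zero row
#' and are flagged.
#'
#' @param results Long enrichment table from [run_gsea()] calls (columns
#'   `pathway`, `group`, `nes`).
#' @param threshold Minimum max-|NES| for a pathway to be retained.
#' @return Numeric matrix (pathways x groups) of z-scores; flagged constant
#'   pathways are listed in `attr(, "flat_pathways")`.
#' @export
nes_heatmap_matrix <- function(results, threshold = 1) {
  dt <- data.table::as.data.table(results)
  wide <- data.table::dcast(dt, pathway ~ group, value.var = "nes")
  m <- as.matrix(wide, rownames = "pathway")
  if (ncol(m) < 2L) stop("need at least 2 groups to z-score pathways")
  keep <- apply(abs(m), 1L, max, na.rm = TRUE) > threshold
  m <- m[keep, , drop = FALSE]
  mu <- rowMeans(m)
  sd_pop <- sqrt(rowMeans((m - mu)^2))
  flat <- rownames(m)[sd_pop == 0]
  sd_pop[sd_pop == 0] <- 1 # constant rows -> z = 0
  z <- (m - mu) / sd_pop
  attr(z, "flat_pathways") <- flat
  z
}
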