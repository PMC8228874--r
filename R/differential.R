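#' Per-gene two-group differential expression with Bonferroni adjustment
#'
#' Welch's t test on log2 expression, gene by gene, with an optional
#' shrinkage of per-group variances toward their across-gene mean (a light
#' empirical-Bayes stabilizer for small groups) and a variance floor so that
#' degenerate zero-variance genes still yield a finite statistic. log2FC is
#' focal-group mean minus reference-group mean. p-values are Bonferroni-
#' adjusted over the number of tested genes, and each gene is assigned the
#' volcano category of [volcano_classify()] (on the adjusted p by default).
#'
#' @param expr Genes x samples log2 matrix with rownames.
#' @param labels Two-group assignment over columns; NA drops a sample.
#' @param focal Focal group (positive log2FC = up in this group); defaults
#'   to the first factor level.
#' @param shrink Weight in `[0, 1]` pulling each gene's group variance
#'   toward the mean variance of that group (0 = plain Welch).
#' @param var_floor Minimum per-group standard deviation.
#' @param p_for_category `"p_adj"` (default) or `"p_raw"`: which p-value
#'   feeds the volcano categorization.
#' @return data.table: `gene`, `log2fc`, `t`, `df`, `p_raw`, `p_adj`,
#'   `category`; options recorded in attributes.
#' @export
de_test <- function(expr, labels, focal = NULL, shrink = 0,
                    var_floor = 0.05, p_for_category = c("p_adj", "p_raw")) {
  p_for_category <- match.arg(p_for_category)
  stopifnot(is.matrix(expr), !is.null(rownames(expr)),
            shrink >= 0, shrink <= 1)
  labels <- as.factor(labels)
  keep <- !is.na(labels)
  expr <- expr[, keep, drop = FALSE]
  labels <- droplevels(labels[keep])
  if (nlevels(labels) != 2L) stop("labels must define exactly two groups")
  if (is.null(focal)) focal <- levels(labels)[1]
  g1 <- expr[, labels == focal, drop = FALSE]
  g2 <- expr[, labels != focal, drop = FALSE]
  n1 <- ncol(g1); n2 <- ncol(g2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  v1 <- apply(g1, 1L, stats::var)
  v2 <- apply(g2, 1L, stats::var)
  if (shrink > 0) {
    v1 <- (1 - shrink) * v1 + shrink * mean(v1)
    v2 <- (1 - shrink) * v2 + shrink * mean(v2)
  }
  v1 <- pmax(v1, var_floor^2)
  v2 <- pmax(v2, var_floor^2)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p_raw <- 2 * stats::pt(-abs(tstat), df)
  # exactly identical degenerate genes: no evidence either way
  degenerate <- (m1 == m2) & (v1 == var_floor^2) & (v2 == var_floor^2)
  p_raw[degenerate] <- 1
  p_adj <- stats::p.adjust(p_raw, method = "bonferroni")
  lfc <- m1 - m2
  p_cat <- if (p_for_category == "p_adj") p_adj else p_raw
  out <- data.table::data.table(
    gene = rownames(expr), log2fc = lfc, t = tstat, df = df,
    p_raw = p_raw, p_adj = p_adj,
    category = volcano_classify(lfc, p_cat))
  data.table::setattr(out, "focal", focal)
  data.table::setattr(out, "shrink", shrink)
  data.table::setattr(out, "p_for_category", p_for_category)
  out[]
}

#' Volcano-plot category for a gene
#'
#' Categories follow the customary display thresholds on |log2FC| at
#' significance `p < alpha`: strictly above 2 is `red`, strictly between
#' 1.5 and 2 is `darkblue`, otherwise `lightblue`; non-significant genes are
#' `ns`. Boundary values are read literally: |log2FC| exactly 2 is
#' `darkblue`, exactly 1.5 is `lightblue`.
#'
#' @param log2fc,p Numeric vectors (recycled to a common length).
#' @param lfc_strong,lfc_moderate Category boundaries on |log2FC|.
#' @param alpha Significance threshold on `p`.
#' @return Character vector in `{red, darkblue, lightblue, ns}`.
#' @export
volcano_classify <- function(log2fc, p, lfc_strong = 2, lfc_moderate = 1.5,
                             alpha = 0.05) {
  af <- abs(log2fc)
  out <- rep("ns", length(af))
  sig <- is.finite(p) & p < alpha
  out[sig & af > lfc_strong] <- "red"
  out[sig & af > lfc_moderate & af <= lfc_strong] <- "darkblue"
  out[sig & af <= lfc_moderate] <- "lightblue"
  out
}

#' Three-way partition of two target gene sets
#'
#' @param set_a,set_b Character vectors of genes.
#' @return List with `a_only`, `shared`, `b_only` (each sorted, unique).
#' @export
target_overlap <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  list(a_only = sort(setdiff(a, b)),
       shared = sort(intersect(a, b)),
       b_only = sort(setdiff(b, a)))
}
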