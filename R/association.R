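#' Rank correlation between two marker series
#'
#' Spearman's r_s (midranks for ties) or Kendall's tau-b (tie-corrected),
#' with a two-sided p-value. Missing values are removed pairwise, matching
#' compartment-specific tissue dropout.
#'
#' @param x,y Numeric vectors of equal length.
#' @param method `"spearman"` or `"kendall"` (tau-b).
#' @param name_a,name_b Optional variable names carried into the result.
#' @return One-row data.table: `variable_a`, `variable_b`, `method`,
#'   `estimate`, `p_value`, `n`, `flagged` (TRUE when the coefficient is
#'   undefined, e.g. a constant input).
#' @export
rank_correlation <- function(x, y, method = c("spearman", "kendall"),
                             name_a = "x", name_b = "y") {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  flagged <- FALSE
  if (n < 3L || length(unique(x)) < 2L || length(unique(y)) < 2L) {
    est <- NA_real_; p <- NA_real_; flagged <- TRUE
  } else {
    ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
    est <- unname(ct$estimate)
    p <- ct$p.value
  }
  data.table::data.table(variable_a = name_a, variable_b = name_b,
                         method = method, estimate = est, p_value = p,
                         n = n, flagged = flagged)
}

#' Pairwise rank-correlation grid over (marker, compartment) parameters
#'
#' @param densities Per-sample density table from [average_replicates()].
#' @param method Correlation method, see [rank_correlation()].
#' @param samples Optional subset of sample ids (e.g. primary tumors only).
#' @return List with `long` (all pairs, one row each) and `matrix`
#'   (symmetric coefficient matrix, parameters in the short `CD68s` form).
#' @export
correlation_matrix <- function(densities, method = c("spearman", "kendall"),
                               samples = NULL) {
  method <- match.arg(method)
  dt <- data.table::as.data.table(densities)
  if (!is.null(samples)) dt <- dt[sample_id %in% samples]
  dt[, param := paste0(marker, ifelse(compartment == "stroma", "s", "t"))]
  wide <- data.table::dcast(dt, sample_id ~ param, value.var = "density")
  params <- setdiff(names(wide), "sample_id")
  mat <- matrix(NA_real_, length(params), length(params),
                dimnames = list(params, params))
  diag(mat) <- 1
  rows <- list()
  for (i in seq_along(params)) for (j in seq_len(i - 1L)) {
    r <- rank_correlation(wide[[params[j]]], wide[[params[i]]], method,
                          name_a = params[j], name_b = params[i])
    rows[[length(rows) + 1L]] <- r
    mat[params[i], params[j]] <- mat[params[j], params[i]] <- r$estimate
  }
  list(long = data.table::rbindlist(rows), matrix = mat)
}

#' Label the strength of a correlation coefficient
#'
#' Fixed, configurable bands (defaults: below 0.4 weak, 0.4-0.7 moderate,
#' above 0.7 strong) applied to the absolute coefficient.
#'
#' @param r Correlation coefficient(s).
#' @param bands Upper bounds of the weak and moderate bands.
#' @export
correlation_strength <- function(r, bands = c(weak = 0.4, moderate = 0.7)) {
  cut(abs(r), breaks = c(-Inf, bands, Inf),
      labels = c("weak", "moderate", "strong"))
}

#' Mann-Whitney U test for two independent groups
#'
#' Reports the U statistic of group `a` (and of `b`; they sum to
#' `n_a * n_b`). Small samples (both groups at most `exact_max`) get an
#' exact two-sided p by full enumeration of group assignments, which remains
#' valid under ties; larger samples use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param exact Force the exact (TRUE) or asymptotic (FALSE) p; default
#'   NULL chooses exact when both groups have at most `exact_max` values.
#' @param exact_max Size bound per group for the default exact rule.
#' @return List with `U_a`, `U_b`, `p_value`, `method`.
#' @export
two_group_test <- function(a, b, exact = NULL, exact_max = 8L) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) stop("both groups must be non-empty")
  if (is.null(exact)) exact <- (na <= exact_max && nb <= exact_max)
  v <- c(a, b)
  r <- rank(v)
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  u_b <- na * nb - u_a
  if (exact) {
    sel <- utils::combn(na + nb, na)
    u_all <- apply(sel, 2L, function(idx) sum(r[idx]) - na * (na + 1) / 2)
    p <- 2 * min(mean(u_all <= u_a), mean(u_all >= u_a))
    p <- min(1, p)
    method <- "exact (enumeration)"
  } else {
    mu <- na * nb / 2
    ties <- table(v)
    tie_term <- sum(ties^3 - ties) / ((na + nb) * (na + nb - 1))
    sigma2 <- na * nb / 12 * ((na + nb + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u_a - mu - sign(u_a - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal approximation, tie-corrected"
  }
  list(U_a = u_a, U_b = u_b, p_value = p, method = method)
}

#' Wilcoxon matched-pairs signed-rank test for replicate cores
#'
#' Used to check that core A and core B of the same tumor give exchangeable
#' densities before averaging them. Zero differences are dropped; if every
#' pair is tied the test is vacuous and p = 1 with a warning.
#'
#' @param core_a,core_b Paired numeric vectors.
#' @return List with `W_pos`, `W_neg` (signed-rank sums), `statistic`
#'   (= `W_pos`, the conventional V), `n_used`, `p_value`.
#' @export
paired_replicate_test <- function(core_a, core_b) {
  if (length(core_a) != length(core_b)) stop("cores must be paired")
  ok <- is.finite(core_a) & is.finite(core_b)
  d <- core_a[ok] - core_b[ok]
  d <- d[d != 0]
  if (length(d) == 0L) {
    warning("all paired differences are zero; test is vacuous")
    return(list(W_pos = 0, W_neg = 0, statistic = 0, n_used = 0L, p_value = 1))
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  p <- suppressWarnings(stats::wilcox.test(d)$p.value)
  list(W_pos = w_pos, W_neg = w_neg, statistic = w_pos,
       n_used = length(d), p_value = p)
}
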