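library(data.table)

# Small cohort spec for fast tests; study-condition defaults otherwise.
small_cohort_spec <- function(n_patients = 12L, seed = 1L, ...) {
  cohort_spec(n_patients = n_patients, seed = seed, ...)
}

small_panel <- function(n_genes = 300L, effect_size = 1.5, noise_sd = 1,
                        calibrated = NULL, ...) {
  panel_spec(n_genes = n_genes,
             module_sizes = c(immune = 40L, proliferation = 40L,
                              neuroendocrine = 20L),
             effect_size = effect_size, noise_sd = noise_sd,
             calibrated = calibrated, ...)
}

# Independent running-sum oracle: walk the whole ranked list.
brute_force_es <- function(scores, genes, set, p) {
  n <- length(genes)
  hits <- genes %in% set
  w <- abs(scores)^p
  tot <- sum(w[hits])
  inc <- ifelse(hits, if (tot > 0) w / tot else 1 / sum(hits),
                -1 / (n - sum(hits)))
  rs <- cumsum(inc)
  list(es = rs[which.max(abs(rs))], curve = rs)
}

# Independent truth-table evaluation of the oasis/desert rule as quoted.
oracle_phenotype <- function(cd45s, cd45t, cd3s, cd3t) {
  h <- function(x) identical(x, "HIGH")
  if (anyNA(c(cd45s, cd45t, cd3s, cd3t))) return("ambiguous")
  oasis <- (h(cd45s) || h(cd45t)) && (h(cd3s) || h(cd3t))
  desert <- (!h(cd3s) && !h(cd3t)) && (!h(cd45s) || !h(cd45t))
  if (oasis && desert) stop("oracle: rules overlap")
  if (oasis) "oasis" else if (desert) "desert" else "ambiguous"
}

# Mann-Whitney U of group a plus exact two-sided p by independent
# enumeration over all group assignments of the pooled values.
oracle_mann_whitney <- function(a, b) {
  n <- length(a) + length(b)
  na <- length(a)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  sel <- utils::combn(n, na)
  u_all <- numeric(ncol(sel))
  for (i in seq_len(ncol(sel))) {
    u_all[i] <- sum(r[sel[, i]]) - na * (na + 1) / 2
  }
  list(U = u_obs,
       p = min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))))
}
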