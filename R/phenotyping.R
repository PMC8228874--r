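#' Median-absolute-deviation cutoff for biomarker dichotomization
#'
#' The threshold is `median(x) + c * MAD(x)` with the raw (unscaled) MAD,
#' `median(|x - median(x)|)`. The default `c = 0` is a median split; `c` is
#' exposed because published cutoff tables rarely state the multiplier.
#'
#' @param values Numeric vector of per-sample biomarker values (NAs dropped).
#' @param c MAD multiplier, default 0.
#' @return A list of class `"tme_cutoff"` with `threshold`, `median`, `mad`
#'   and `c`.
#' @examples
#' mad_cutoff(c(1, 2, 3, 4, 100), c = 2)$threshold # 5
#' @export
mad_cutoff <- function(values, c = 0) {
  x <- values[is.finite(values)]
  if (length(x) < 2L) stop("need at least 2 finite values for a cutoff")
  med <- stats::median(x)
  m <- stats::median(abs(x - med))
  if (m == 0 && length(unique(x)) == 1L) {
    warning("all values identical; dichotomization at this cutoff is degenerate")
  }
  structure(list(threshold = med + c * m, median = med, mad = m, c = c),
            class = "tme_cutoff")
}

#' @export
print.tme_cutoff <- function(x, ...) {
  cat(sprintf("MAD cutoff: threshold %.4g (median %.4g, MAD %.4g, c = %g)\n",
              x$threshold, x$median, x$mad, x$c))
  invisible(x)
}

#' Dichotomize biomarker values into HIGH/LOW calls
#'
#' Continuous values: HIGH iff strictly above the threshold (ties at the
#' threshold are LOW, a deterministic rule consistent with the ordinal
#' convention below). Ordinal scores 0-3: HIGH iff score is 2 or 3.
#' Missing values stay missing.
#'
#' @param value Numeric vector of values or ordinal scores.
#' @param cutoff A `tme_cutoff` (or single numeric threshold); ignored when
#'   `ordinal = TRUE`.
#' @param ordinal Treat `value` as a 0-3 ordinal score.
#' @return Character vector of `"HIGH"`/`"LOW"`, NA preserved.
#' @export
dichotomize <- function(value, cutoff = NULL, ordinal = FALSE) {
  if (ordinal) {
    out <- ifelse(value >= 2, "HIGH", "LOW")
  } else {
    thr <- if (inherits(cutoff, "tme_cutoff")) cutoff$threshold else cutoff
    if (is.null(thr) || !is.finite(thr)) stop("a finite cutoff is required")
    out <- ifelse(value > thr, "HIGH", "LOW")
  }
  out[!is.finite(value)] <- NA_character_
  out
}

#' Build a per-sample HIGH/LOW annotation table from densities and scores
#'
#' Applies a MAD cutoff per (marker, compartment) parameter across samples,
#' naming parameters in the conventional short form (`CD68s` = stroma,
#' `CD68t` = tumor nest). Ordinal parameters (default: CD33) are dichotomized
#' by the score >= 2 rule instead of a density cutoff.
#'
#' @param densities Per-sample density table from [average_replicates()].
#' @param scores Optional data.table of ordinal scores with columns
#'   `sample_id`, `marker`, `compartment`, `score`.
#' @param c MAD multiplier passed to [mad_cutoff()].
#' @param samples Optional character vector restricting the samples on which
#'   cutoffs are computed (e.g. primary tumors only); calls are still emitted
#'   for all samples in the table.
#' @return List with `annotation` (wide data.table, one row per sample, one
#'   HIGH/LOW/NA column per parameter) and `cutoffs` (data.table of
#'   parameter, threshold, median, mad, c).
#' @export
annotate_markers <- function(densities, scores = NULL, c = 0, samples = NULL) {
  dt <- data.table::as.data.table(densities)
  dt[, param := paste0(marker, ifelse(compartment == "stroma", "s", "t"))]
  cuts <- list()
  calls <- list()
  for (p in sort(unique(dt$param))) {
    sub <- dt[param == p]
    base <- if (is.null(samples)) sub else sub[sample_id %in% samples]
    ct <- mad_cutoff(base$density, c = c)
    cuts[[p]] <- data.table::data.table(param = p, threshold = ct$threshold,
                                        median = ct$median, mad = ct$mad, c = c)
    calls[[p]] <- data.table::data.table(sample_id = sub$sample_id, param = p,
                                         call = dichotomize(sub$density, ct))
  }
  if (!is.null(scores)) {
    sc <- data.table::as.data.table(scores)
    sc[, param := paste0(marker, ifelse(compartment == "stroma", "s", "t"))]
    for (p in sort(unique(sc$param))) {
      sub <- sc[param == p]
      calls[[p]] <- data.table::data.table(sample_id = sub$sample_id, param = p,
                                           call = dichotomize(sub$score, ordinal = TRUE))
    }
  }
  long <- data.table::rbindlist(calls)
  wide <- data.table::dcast(long, sample_id ~ param, value.var = "call")
  list(annotation = wide, cutoffs = data.table::rbindlist(cuts))
}

#' Classify samples into immune-oasis / immune-desert phenotypes
#'
#' A sample is immune-oasis when it is HIGH for stromal or intratumoral CD45
#' density AND HIGH for stromal or intratumoral CD3 density. It is
#' immune-desert when it is LOW for both stromal and intratumoral CD3 AND LOW
#' for stromal or intratumoral CD45. The two rules are mutually exclusive but
#' not exhaustive; the remainder is labelled ambiguous, as is any sample with
#' a missing required call (with a reason).
#'
#' @param annotation Wide annotation table with columns `sample_id`, `CD45s`,
#'   `CD45t`, `CD3s`, `CD3t` (HIGH/LOW/NA).
#' @return data.table with `sample_id`, `phenotype`
#'   (oasis/desert/ambiguous) and `reason`.
#' @export
classify_immune_phenotype <- function(annotation) {
  ann <- data.table::as.data.table(annotation)
  need <- c("CD45s", "CD45t", "CD3s", "CD3t")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation lacks required calls: ", paste(miss, collapse = ", "))
  one <- function(cd45s, cd45t, cd3s, cd3t) {
    calls <- c(cd45s, cd45t, cd3s, cd3t)
    if (anyNA(calls)) {
      return(c("ambiguous", "missing required CD45/CD3 call"))
    }
    hi <- calls == "HIGH"
    oasis <- (hi[1] || hi[2]) && (hi[3] || hi[4])
    desert <- (!hi[3] && !hi[4]) && (!hi[1] || !hi[2])
    if (oasis) c("oasis", "") else if (desert) c("desert", "")
    else c("ambiguous", "matches neither rule")
  }
  res <- mapply(one, ann$CD45s, ann$CD45t, ann$CD3s, ann$CD3t)
  data.table::data.table(sample_id = ann$sample_id,
                         phenotype = res[1, ], reason = res[2, ])
}

#' Macrophage-high / macrophage-low grouping
#'
#' The grouping used alongside the phenotype calls: a sample is
#' macrophage-high when at least `min_frac` of its available macrophage-
#' related parameter calls are HIGH. The parameter list and fraction are
#' configurable; the default list follows the macrophage-related parameters
#' (CD68, CD163 in both compartments, stromal CD33 and tumor-cell MHCII).
#'
#' @param annotation Wide annotation table (HIGH/LOW/NA columns).
#' @param params Parameters entering the rule; only those present in the
#'   table are used, but at least one must be present.
#' @param min_frac Minimum fraction of available calls that must be HIGH.
#' @return data.table with `sample_id`, `macrophage_class`, `n_high`,
#'   `n_available`.
#' @export
macrophage_class <- function(annotation,
                             params = c("CD68s", "CD68t", "CD163s", "CD163t",
                                        "CD33s", "MHCIIt"),
                             min_frac = 0.5) {
  ann <- data.table::as.data.table(annotation)
  use <- intersect(params, names(ann))
  if (!length(use)) stop("none of the macrophage parameters present in annotation")
  m <- as.matrix(ann[, ..use])
  n_high <- rowSums(m == "HIGH", na.rm = TRUE)
  n_avail <- rowSums(!is.na(m))
  if (any(n_avail == 0)) stop("sample(s) with all macrophage calls missing")
  data.table::data.table(
    sample_id = ann$sample_id,
    macrophage_class = ifelse(n_high / n_avail >= min_frac,
                              "macrophage_high", "macrophage_low"),
    n_high = n_high, n_available = n_avail)
}
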