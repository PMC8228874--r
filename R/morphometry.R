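#' Convert a cell count and a measured area to a cell density
#'
#' Areas are annotated in square micrometers on the image; densities are
#' reported in cells per square millimeter, so the area is scaled by 1e-6.
#'
#' @param cell_count Non-negative integer count(s) of positive cells.
#' @param area_um2 Positive measured area(s) in square micrometers.
#' @return Density in cells/mm^2, vectorized over the inputs.
#' @examples
#' cell_density(50, 5e5) # 100 cells/mm^2
#' @export
cell_density <- function(cell_count, area_um2) {
  if (any(!is.finite(area_um2)) || any(area_um2 <= 0)) {
    stop("area_um2 must be positive and finite: invalid area annotation")
  }
  if (any(!is.finite(cell_count)) || any(cell_count < 0)) {
    stop("cell_count must be non-negative and finite")
  }
  cell_count / (area_um2 * 1e-6)
}

#' Average replicate sections and cores into per-sample densities
#'
#' Two sections are cut from each tissue-microarray core; primary tumors
#' contribute two cores (A and B), lymph-node metastases one. Section
#' densities are averaged within a core, then core means are averaged
#' (unweighted) into one density per (sample, marker, compartment).
#' Compartments absent from every core of a sample yield no row (missing,
#' never zero), so downstream cutoffs are not biased by structural zeros.
#'
#' @param counts A data.frame/data.table of compartment counts with columns
#'   `sample_id`, `core_id`, `section_id`, `marker`, `compartment`,
#'   `cell_count`, `area_um2`.
#' @return A data.table with columns `sample_id`, `marker`, `compartment`,
#'   `density` (cells/mm^2), one row per observed combination.
#' @export
average_replicates <- function(counts) {
  counts <- as_count_table(counts)
  counts[, density := cell_density(cell_count, area_um2)]
  core_means <- counts[, .(density = mean(density)),
                       by = .(sample_id, marker, compartment, core_id)]
  out <- core_means[, .(density = mean(density)),
                    by = .(sample_id, marker, compartment)]
  data.table::setkey(out, sample_id, marker, compartment)
  out[]
}

#' Semi-quantitative ordinal score for sparse myeloid (CD33) counts
#'
#' Counts are binned 0 (0 cells), 1 (1-10), 2 (11-20), 3 (21 or more cells).
#' A count of exactly 21 scores 3, so the bins partition the integers.
#'
#' @param cell_count Non-negative integer count(s) per core compartment.
#' @return Integer score(s) in 0..3.
#' @export
cd33_score <- function(cell_count) {
  if (any(!is.finite(cell_count)) || any(cell_count < 0)) {
    stop("cell_count must be a non-negative integer")
  }
  if (any(cell_count != round(cell_count))) {
    stop("cell_count must be integer-valued")
  }
  findInterval(cell_count, c(1, 11, 21))
}

#' Immune-cell composition relative to the pan-leukocyte compartment
#'
#' Expresses each marker's density as a fraction of the CD45+ (pan-leukocyte)
#' density, per group and compartment. Fractions need not sum to one since
#' markers overlap (e.g. CD163+ cells are a subset of CD68+ macrophages).
#'
#' @param densities Per-sample density table as returned by
#'   [average_replicates()].
#' @param groups Named character vector mapping `sample_id` to a group label
#'   (e.g. NE subtype). Samples without a label are dropped.
#' @param compartment Compartment(s) to include; default both.
#' @param mode `"ratio_of_sums"` (default; group-summed marker density over
#'   group-summed CD45 density, robust to samples with tiny CD45) or
#'   `"mean_of_ratios"` (average of per-sample fractions).
#' @param reference_marker Denominator marker, default `"CD45"`.
#' @return data.table with `group`, `compartment`, `marker`, `fraction`, and
#'   a logical `flagged` column set when the reference aggregate is zero
#'   (fraction undefined, reported as NA).
#' @export
composition <- function(densities,
                        groups,
                        compartment = c("stroma", "tumor_nest"),
                        mode = c("ratio_of_sums", "mean_of_ratios"),
                        reference_marker = "CD45") {
  mode <- match.arg(mode)
  comps <- compartment
  dt <- data.table::as.data.table(densities)
  dt <- dt[compartment %in% comps]
  dt[, group := groups[sample_id]]
  dt <- dt[!is.na(group)]
  ref <- dt[marker == reference_marker,
            .(sample_id, compartment, ref_density = density, group)]
  if (nrow(ref) == 0L) stop("reference marker '", reference_marker, "' absent")
  mk <- dt[marker != reference_marker]
  merged <- merge(mk, ref[, .(sample_id, compartment, ref_density)],
                  by = c("sample_id", "compartment"))
  if (mode == "ratio_of_sums") {
    out <- merged[, .(fraction = sum(density) / sum(ref_density),
                      flagged = sum(ref_density) == 0),
                  by = .(group, compartment, marker)]
  } else {
    merged <- merged[ref_density > 0 | density > 0]
    out <- merged[, .(fraction = mean(density / ref_density),
                      flagged = any(ref_density == 0)),
                  by = .(group, compartment, marker)]
  }
  out[flagged == TRUE, fraction := NA_real_]
  data.table::setkey(out, group, compartment, marker)
  out[]
}

# Validate and coerce a raw compartment-count table.
as_count_table <- function(counts) {
  need <- c("sample_id", "core_id", "section_id", "marker", "compartment",
            "cell_count", "area_um2")
  counts <- data.table::as.data.table(counts)
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("count table lacks columns: ", paste(miss, collapse = ", "))
  if (any(counts$cell_count < 0)) stop("negative cell_count in count table")
  if (any(counts$area_um2 <= 0)) stop("non-positive area_um2 in count table")
  bad <- setdiff(unique(counts$compartment), c("stroma", "tumor_nest"))
  if (length(bad)) stop("unknown compartment(s): ", paste(bad, collapse = ", "))
  data.table::copy(counts)
}
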