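#' Read a compartment count table (CSV or TSV)
#'
#' Expected header: `sample_id, core_id, section_id, marker, compartment,
#' cell_count, area_um2`. Rows with negative counts or non-positive areas
#' are rejected at parse.
#'
#' @param path File path; the delimiter is sniffed by [data.table::fread()].
#' @return Validated data.table.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("count table not found: ", path)
  as_count_table(data.table::fread(path))
}

#' @rdname read_counts
#' @param counts Count table to write.
#' @export
write_counts <- function(counts, path) {
  data.table::fwrite(as_count_table(counts), path, sep = "\t")
  invisible(path)
}

#' Read a genes x samples expression matrix from TSV
#'
#' First column = gene identifiers (any name), remaining columns = samples.
#' Duplicate gene identifiers are an error.
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  dt <- data.table::fread(path, header = TRUE)
  genes <- as.character(dt[[1]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) stop("duplicate gene identifier(s) in expression table: ",
                        paste(utils::head(dup, 5L), collapse = ", "))
  m <- as.matrix(dt[, -1])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- genes
  m
}

#' @rdname read_expression
#' @param expr Matrix to write (genes in rows).
#' @export
write_expression <- function(expr, path) {
  dt <- data.table::data.table(gene = rownames(expr))
  dt <- cbind(dt, data.table::as.data.table(expr))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated member genes.
#' Empty member lists are reported with their line number.
#'
#' @param path File path.
#' @return Named list of character vectors; descriptions in
#'   `attr(, "descriptions")`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop("malformed GMT line ", i, ": fewer than 3 tab-separated fields")
    }
    sets[[parts[1]]] <- unique(parts[-(1:2)])
    desc[parts[1]] <- parts[2]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector (recycled) for field 2.
#' @export
write_gmt <- function(sets, path, descriptions = "na") {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("all gene sets must be named")
  }
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write an interaction edge table (3-column TSV)
#'
#' Columns `gene_a`, `gene_b`, `score` with scores in (0, 1]; edges are
#' canonicalized (undirected, deduplicated) on read.
#'
#' @param path File path.
#' @export
read_edges <- function(path) {
  if (!file.exists(path)) stop("edge table not found: ", path)
  as_interaction_edges(data.table::fread(path))
}

#' @rdname read_edges
#' @param edges Edge table to write.
#' @export
write_edges <- function(edges, path) {
  data.table::fwrite(as_interaction_edges(edges), path, sep = "\t")
  invisible(path)
}

#' Read / write a wide HIGH/LOW annotation table (CSV)
#'
#' One row per sample (`sample_id` column), one column per (marker,
#' compartment) parameter in the short form (`CD68s`, `CD45t`, ...), values
#' HIGH/LOW or empty for missing.
#'
#' @param path File path.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation table not found: ", path)
  dt <- data.table::fread(path, na.strings = c("", "NA"))
  if (!"sample_id" %in% names(dt)) stop("annotation table needs a sample_id column")
  for (col in setdiff(names(dt), "sample_id")) {
    vals <- dt[[col]]
    bad <- !is.na(vals) & !vals %in% c("HIGH", "LOW")
    if (any(bad)) stop("annotation column ", col, " has value(s) other than HIGH/LOW")
  }
  dt
}

#' @rdname read_annotation
#' @param annotation Table to write.
#' @export
write_annotation <- function(annotation, path) {
  data.table::fwrite(data.table::as.data.table(annotation), path)
  invisible(path)
}
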