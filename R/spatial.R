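# Region-wise phenotype density quantification from segmented-cell tables.
# Cells arrive already binarized (marker flags 0/1) with a region label from
# the upstream tissue classification; densities are counts over declared
# region areas in mm^2.

#' Segmented-cell table with declared region areas
#'
#' Cells whose region label is not in `region_areas` are excluded and counted
#' in the `qc_excluded` attribute, mirroring the exclusion of necrosis and
#' artifact regions upstream.
#'
#' @param cells data.frame with columns `x_um`, `y_um`, `region` and one 0/1
#'   column per marker.
#' @param region_areas named positive areas in mm^2, one per region.
#' @return A `cell_table` (data.frame subclass carrying `region_areas`).
#' @export
cell_table <- function(cells, region_areas) {
  stopifnot(is.data.frame(cells))
  if (is.null(names(region_areas)) || any(region_areas <= 0))
    stop("region_areas must be named and positive")
  need <- c("x_um", "y_um", "region")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("cell table missing column(s): ",
                         paste(miss, collapse = ", "))
  markers <- setdiff(names(cells), need)
  for (mk in markers) {
    if (!all(cells[[mk]] %in% c(0, 1)))
      stop("marker column '", mk, "' must be binary 0/1")
  }
  known <- cells$region %in% names(region_areas)
  excluded <- sum(!known)
  cells <- cells[known, , drop = FALSE]
  rownames(cells) <- NULL
  structure(cells, region_areas = region_areas, qc_excluded = excluded,
            markers = markers, class = c("cell_table", "data.frame"))
}

#' Phenotype query over marker flags
#'
#' @param positive markers required positive (e.g. T cell: CD3+ SOX10-).
#' @param negative markers required negative.
#' @return A `phenotype_query`.
#' @export
phenotype_query <- function(positive, negative = character()) {
  positive <- as.character(positive); negative <- as.character(negative)
  if (length(intersect(positive, negative)))
    stop("a marker cannot be required both positive and negative")
  structure(list(positive = positive, negative = negative),
            class = "phenotype_query")
}

match_phenotype <- function(cells, query) {
  stopifnot(inherits(query, "phenotype_query"))
  ok <- rep(TRUE, nrow(cells))
  for (mk in query$positive) ok <- ok & cells[[mk]] == 1
  for (mk in query$negative) ok <- ok & cells[[mk]] == 0
  ok
}

#' Phenotype density in a region (cells per mm^2)
#'
#' @param cells a [cell_table()].
#' @param query a [phenotype_query()].
#' @param region a declared region name, or "total" for summed counts over
#'   summed areas.
#' @return Density in cells/mm^2.
#' @export
region_density <- function(cells, query, region = "total") {
  areas <- attr(cells, "region_areas")
  ok <- match_phenotype(cells, query)
  if (identical(region, "total"))
    return(sum(ok) / sum(areas))
  if (!region %in% names(areas)) stop("unknown region: ", region)
  sum(ok & cells$region == region) / areas[[region]]
}

#' Ratio of two phenotype counts within a region
#'
#' @param cells a [cell_table()].
#' @param numerator,denominator [phenotype_query()]s.
#' @param region region name or "total".
#' @return List: `ratio` (NA when the denominator count is 0) and
#'   `undefined` flag.
#' @export
phenotype_ratio <- function(cells, numerator, denominator, region = "total") {
  areas <- attr(cells, "region_areas")
  in_region <- if (identical(region, "total")) rep(TRUE, nrow(cells)) else {
    if (!region %in% names(areas)) stop("unknown region: ", region)
    cells$region == region
  }
  num <- sum(match_phenotype(cells, numerator) & in_region)
  den <- sum(match_phenotype(cells, denominator) & in_region)
  if (den == 0) return(list(ratio = NA_real_, undefined = TRUE))
  list(ratio = num / den, undefined = FALSE)
}

#' Density table over named phenotypes and all declared regions
#'
#' @param cells a [cell_table()].
#' @param queries named list of [phenotype_query()]s.
#' @return data.frame: phenotype, region, count, area_mm2, density.
#' @export
density_table <- function(cells, queries) {
  if (!length(queries)) stop("query list must be nonempty")
  if (is.null(names(queries)) || anyDuplicated(names(queries)))
    stop("queries must have unique names")
  areas <- attr(cells, "region_areas")
  rows <- list()
  for (ph in names(queries)) {
    ok <- match_phenotype(cells, queries[[ph]])
    for (rg in names(areas)) {
      cnt <- sum(ok & cells$region == rg)
      rows[[length(rows) + 1L]] <- data.frame(
        phenotype = ph, region = rg, count = cnt, area_mm2 = areas[[rg]],
        density = cnt / areas[[rg]], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Canonical phenotype queries used throughout the analysis
#'
#' T cell: CD3+ SOX10-; CD8 T cell: CD3+ CD8+ SOX10-; Treg: CD3+ FOXP3+
#' SOX10-; activated Treg additionally ICOS+; tumor cell: SOX10+.
#' @return Named list of [phenotype_query()]s.
#' @export
default_phenotype_queries <- function() {
  list(
    t_cell = phenotype_query("CD3", "SOX10"),
    cd8_t = phenotype_query(c("CD3", "CD8"), "SOX10"),
    treg = phenotype_query(c("CD3", "FOXP3"), "SOX10"),
    treg_icos = phenotype_query(c("CD3", "FOXP3", "ICOS"), "SOX10"),
    tumor = phenotype_query("SOX10"))
}

#' Read / write segmented-cell CSV
#'
#' Columns: x_um, y_um, region, one 0/1 column per marker. Region areas ride
#' along in a small JSON sidecar named `<path>.areas.json`.
#'
#' @param path CSV path.
#' @return `read_cell_table_csv` returns a [cell_table()].
#' @export
read_cell_table_csv <- function(path) {
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  areas <- unlist(jsonlite::read_json(paste0(path, ".areas.json")))
  cell_table(cells, areas)
}

#' @rdname read_cell_table_csv
#' @param cells a [cell_table()].
#' @export
write_cell_table_csv <- function(cells, path) {
  utils::write.csv(as.data.frame(cells), path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(as.list(attr(cells, "region_areas")),
                       paste0(path, ".areas.json"), auto_unbox = TRUE)
  invisible(path)
}
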