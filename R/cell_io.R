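# Cell-table input/output and the global (whole-compartment) indicators.
#
# The expected input is the tabular export of a cell-detection /
# classification step run on a scanned IHC slide: one row per detected
# cell with micrometer coordinates, a tissue-compartment label
# (tumor / stroma / background) and per-marker positivity flags.

#' Known marker columns
#'
#' Binary positivity markers recognised by the default schema. HER2 is
#' handled separately through its 4-level staining class (`her2_class`).
#' @keywords internal
MARKER_NAMES <- c("er", "pr", "ki67", "cd8", "satb1", "hif1a")

COMPARTMENTS <- c("tumor", "stroma", "background")
HER2_CLASSES <- c("0", "1+", "2+", "3+")

#' Default column-name mapping for cell tables
#'
#' Vendor exports differ in column naming; `read_cell_table()` takes a
#' schema so any dialect can be mapped onto the internal representation.
#' The default matches the package's own `write_cell_table()` output.
#'
#' @return A list with entries `case_id`, `x`, `y`, `compartment`,
#'   `her2_class` and a named character vector `markers` mapping internal
#'   marker names to file column names.
#' @export
default_schema <- function() {
  list(
    case_id = "case_id",
    x = "x_um",
    y = "y_um",
    compartment = "compartment",
    her2_class = "her2_class",
    markers = stats::setNames(MARKER_NAMES, MARKER_NAMES)
  )
}

#' Construct a cell map
#'
#' A `cell_map` bundles one case's cell point pattern with its compartment
#' geometry: `cells` (data frame with numeric `x`, `y` in micrometers, a
#' `compartment` label, optional logical marker columns and an optional
#' `her2_class` column), `geometry` (named numeric, compartment areas in
#' mm^2) and the bounding rectangle of the tissue.
#'
#' @param case_id Non-empty case identifier.
#' @param cells Data frame of cell records.
#' @param geometry Named numeric vector of compartment areas in mm^2
#'   (e.g. `c(tumor = 9.4, stroma = 6.2)`), or `NULL` if no density
#'   indicators will be requested.
#' @param bounds Numeric `c(xmin, ymin, xmax, ymax)` in micrometers; when
#'   `NULL` the min/max envelope of the coordinates is used.
#' @return An object of class `cell_map`.
#' @export
cell_map <- function(case_id, cells, geometry = NULL, bounds = NULL) {
  if (!is.character(case_id) || length(case_id) != 1L || !nzchar(case_id)) {
    stop("'case_id' must be a non-empty string")
  }
  cells <- as.data.frame(cells)
  for (col in c("x", "y", "compartment")) {
    if (!col %in% names(cells)) stop("cells table lacks required column '", col, "'")
  }
  if (nrow(cells) > 0L) {
    if (!is.numeric(cells$x) || !is.numeric(cells$y)) {
      stop("cell coordinates must be numeric")
    }
    bad <- which(!is.finite(cells$x) | !is.finite(cells$y) |
                   cells$x < 0 | cells$y < 0)
    if (length(bad)) {
      stop("non-finite or negative coordinate at row ", bad[1L])
    }
    unknown <- which(!cells$compartment %in% COMPARTMENTS)
    if (length(unknown)) {
      stop("unknown compartment label '", cells$compartment[unknown[1L]],
           "' at row ", unknown[1L])
    }
    if ("her2_class" %in% names(cells)) {
      h <- cells$her2_class
      badh <- which(!is.na(h) & !h %in% HER2_CLASSES)
      if (length(badh)) {
        stop("unknown her2_class value '", h[badh[1L]], "' at row ", badh[1L])
      }
    }
    for (m in intersect(MARKER_NAMES, names(cells))) {
      if (!is.logical(cells[[m]])) stop("marker column '", m, "' must be logical")
    }
  }
  if (is.null(bounds)) {
    bounds <- if (nrow(cells) > 0L) {
      c(min(cells$x), min(cells$y), max(cells$x), max(cells$y))
    } else {
      c(0, 0, 0, 0)
    }
  }
  bounds <- as.numeric(bounds)
  if (length(bounds) != 4L || bounds[3L] < bounds[1L] || bounds[4L] < bounds[2L]) {
    stop("'bounds' must be c(xmin, ymin, xmax, ymax) with xmax >= xmin, ymax >= ymin")
  }
  if (nrow(cells) > 0L &&
      (any(cells$x < bounds[1L] | cells$x > bounds[3L]) ||
       any(cells$y < bounds[2L] | cells$y > bounds[4L]))) {
    stop("cell coordinates fall outside 'bounds'")
  }
  if (!is.null(geometry)) {
    geometry <- unlist(geometry)
    if (is.null(names(geometry)) || !all(names(geometry) %in% COMPARTMENTS)) {
      stop("'geometry' must be a named vector of compartment areas (mm^2)")
    }
    if (any(!is.finite(geometry)) || any(geometry < 0)) {
      stop("compartment areas must be finite and non-negative")
    }
  }
  structure(
    list(case_id = case_id, cells = cells, geometry = geometry, bounds = bounds),
    class = "cell_map"
  )
}

#' @export
print.cell_map <- function(x, ...) {
  cat("<cell_map> case", x$case_id, "-", nrow(x$cells), "cells\n")
  cat("  bounds (um):", paste(signif(x$bounds, 6), collapse = ", "), "\n")
  if (!is.null(x$geometry)) {
    cat("  areas (mm^2):",
        paste(sprintf("%s=%.3f", names(x$geometry), x$geometry), collapse = ", "), "\n")
  }
  mk <- intersect(c(MARKER_NAMES, "her2_class"), names(x$cells))
  if (length(mk)) cat("  markers:", paste(mk, collapse = ", "), "\n")
  invisible(x)
}

delim_for_path <- function(path) {
  if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a per-case cell table
#'
#' Reads a delimited cell export (comma- or tab-separated, auto-detected
#' from the file extension), maps its columns through `schema`, validates
#' coordinates and compartment labels, and returns a [cell_map()].
#'
#' @param path Path to a CSV/TSV file.
#' @param schema Column-name mapping, see [default_schema()].
#' @param geometry Optional named compartment-area vector (mm^2) attached
#'   to the returned map.
#' @param case_id Case identifier; defaults to the (unique) value of the
#'   mapped case-id column when present.
#' @param bounds Optional bounding rectangle `c(xmin, ymin, xmax, ymax)`;
#'   inferred from the coordinate envelope when absent.
#' @return A [cell_map()].
#' @export
read_cell_table <- function(path, schema = default_schema(), geometry = NULL,
                            case_id = NULL, bounds = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delim_for_path(path),
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", na.strings = c("NA", ""))
  for (field in c("x", "y", "compartment")) {
    col <- schema[[field]]
    if (!col %in% names(raw)) stop("schema error: missing column '", col, "'")
  }
  n <- nrow(raw)
  num <- function(field) {
    col <- schema[[field]]
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad)) {
      stop("non-numeric value '", raw[[col]][bad[1L]], "' in column '", col,
           "' at row ", bad[1L])
    }
    v
  }
  cells <- data.frame(x = num("x"), y = num("y"),
                      compartment = as.character(raw[[schema$compartment]]),
                      stringsAsFactors = FALSE)
  for (m in names(schema$markers)) {
    col <- schema$markers[[m]]
    if (col %in% names(raw)) cells[[m]] <- parse_flag(raw[[col]], col)
  }
  hcol <- schema$her2_class
  if (!is.null(hcol) && hcol %in% names(raw)) {
    cells$her2_class <- as.character(raw[[hcol]])
  }
  if (is.null(case_id)) {
    ccol <- schema$case_id
    if (!is.null(ccol) && ccol %in% names(raw) && n > 0L) {
      ids <- unique(raw[[ccol]])
      if (length(ids) != 1L) stop("multiple case ids in one file: ", paste(ids, collapse = ", "))
      case_id <- ids
    } else {
      case_id <- sub("\\.[^.]*$", "", basename(path))
    }
  }
  cell_map(case_id, cells, geometry = geometry, bounds = bounds)
}

parse_flag <- function(v, col) {
  out <- rep(NA, length(v))
  out[v %in% c("1", "TRUE", "true", "T")] <- TRUE
  out[v %in% c("0", "FALSE", "false", "F")] <- FALSE
  bad <- which(is.na(out) & !is.na(v))
  if (length(bad)) {
    stop("non-boolean value '", v[bad[1L]], "' in marker column '", col,
         "' at row ", bad[1L])
  }
  as.logical(out)
}

#' Write a cell map to a delimited table
#'
#' One row per cell, stable column order (`case_id`, `x_um`, `y_um`,
#' `compartment`, markers, `her2_class`), marker flags as 0/1, coordinates
#' at full precision. Comma- or tab-separated depending on the extension.
#'
#' @param cellmap A [cell_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cellmap, path) {
  stopifnot(inherits(cellmap, "cell_map"))
  cells <- cellmap$cells
  out <- data.frame(case_id = rep(cellmap$case_id, nrow(cells)),
                    x_um = sprintf("%.17g", cells$x),
                    y_um = sprintf("%.17g", cells$y),
                    compartment = cells$compartment,
                    stringsAsFactors = FALSE)
  if (nrow(cells) == 0L) {
    out <- out[0L, , drop = FALSE]
  }
  for (m in intersect(MARKER_NAMES, names(cells))) {
    out[[m]] <- as.integer(cells[[m]])
  }
  if ("her2_class" %in% names(cells)) out$her2_class <- cells$her2_class
  ok <- tryCatch({
    utils::write.table(out, path, sep = delim_for_path(path), na = "NA",
                       row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ", conditionMessage(e)))
  invisible(path)
}

compartment_cells <- function(cellmap, compartment) {
  compartment <- match.arg(compartment, c("tumor", "stroma"))
  cellmap$cells[cellmap$cells$compartment == compartment, , drop = FALSE]
}

#' Global positivity percentage of a marker within a compartment
#'
#' The percentage of marker-positive cells among all marker-evaluated
#' cells of the compartment. Cells lacking the marker flag (stained on a
#' different serial section) are excluded from the denominator. For
#' `marker = "her2"` a cell counts as positive when its staining class is
#' 2+ or 3+. Background cells never contribute.
#'
#' @param cellmap A [cell_map()].
#' @param marker One of the binary markers or `"her2"`.
#' @param compartment `"tumor"` (default) or `"stroma"`.
#' @return Percentage in \[0, 100\], or `NA_real_` when no cell of the
#'   compartment was evaluated for the marker (undefined, distinct from 0).
#' @export
global_percent <- function(cellmap, marker, compartment = "tumor") {
  stopifnot(inherits(cellmap, "cell_map"))
  cells <- compartment_cells(cellmap, compartment)
  if (identical(marker, "her2")) {
    if (!"her2_class" %in% names(cellmap$cells)) {
      stop("cell map has no 'her2_class' column")
    }
    h <- cells$her2_class
    eval_n <- sum(!is.na(h))
    pos_n <- sum(h %in% c("2+", "3+"))
  } else {
    if (!marker %in% names(cellmap$cells)) {
      stop("cell map has no marker column '", marker, "'")
    }
    f <- cells[[marker]]
    eval_n <- sum(!is.na(f))
    pos_n <- sum(f, na.rm = TRUE)
  }
  if (eval_n == 0L) return(NA_real_)
  100 * pos_n / eval_n
}

#' Cell density of a marker combination within a compartment
#'
#' Count of compartment cells positive for every marker in `markers`
#' (e.g. `c("cd8")` or `c("cd8", "satb1")`) divided by the compartment
#' area in mm^2.
#'
#' @param cellmap A [cell_map()] with geometry.
#' @param markers Character vector of marker names, all of which must be
#'   positive for a cell to count.
#' @param compartment `"tumor"` (default) or `"stroma"`.
#' @return Density in cells/mm^2.
#' @export
cell_density <- function(cellmap, markers, compartment = "tumor") {
  stopifnot(inherits(cellmap, "cell_map"), length(markers) >= 1L)
  compartment <- match.arg(compartment, c("tumor", "stroma"))
  area <- cellmap$geometry[compartment]
  if (is.null(cellmap$geometry) || is.na(area) || area <= 0) {
    stop("no positive '", compartment, "' area in geometry; densities need explicit compartment areas")
  }
  cells <- compartment_cells(cellmap, compartment)
  hit <- rep(TRUE, nrow(cells))
  for (m in markers) {
    if (!m %in% names(cellmap$cells)) stop("cell map has no marker column '", m, "'")
    hit <- hit & !is.na(cells[[m]]) & cells[[m]]
  }
  sum(hit) / as.numeric(area)
}
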