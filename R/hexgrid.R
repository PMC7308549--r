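# Randomly positioned hexagonal tiling of the slide plane.
#
# Pointy-top regular hexagons of side s tile the plane with centers at
#   cx = s*sqrt(3)*(q + r/2) + ox,  cy = s*1.5*r + oy
# in axial coordinates (q, r). Assigning a point to its hexagon is the
# inverse affine map followed by cube rounding; because the hexagons are
# the Voronoi cells of their centers, this equals nearest-center
# assignment.

#' Build a randomly positioned hexagonal grid
#'
#' The grid offset is drawn uniformly over one lattice period (one period
#' of the tiling: `sqrt(3)*side` in x, `3*side` in y) from R's current
#' random number generator, so a fixed `set.seed()` gives a fixed grid.
#'
#' @param bounds Rectangle `c(xmin, ymin, xmax, ymax)` in micrometers.
#' @param side Hexagon side length in micrometers (default 257).
#' @param offset Optional fixed offset `c(ox, oy)`; when `NULL` it is
#'   drawn randomly.
#' @return An object of class `hex_grid`.
#' @export
build_grid <- function(bounds, side = 257, offset = NULL) {
  bounds <- as.numeric(bounds)
  if (length(bounds) != 4L || bounds[3L] <= bounds[1L] || bounds[4L] <= bounds[2L]) {
    stop("'bounds' must be a non-degenerate rectangle c(xmin, ymin, xmax, ymax)")
  }
  if (!is.numeric(side) || length(side) != 1L || !is.finite(side) || side <= 0) {
    stop("'side' must be a positive length in micrometers")
  }
  period <- c(sqrt(3) * side, 3 * side)
  if (is.null(offset)) {
    offset <- stats::runif(2) * period
  } else {
    offset <- as.numeric(offset)
    if (length(offset) != 2L || any(!is.finite(offset))) stop("'offset' must be c(ox, oy)")
    offset <- offset %% period
  }
  structure(
    list(side = side, orientation = "pointy-top", offset = offset, bounds = bounds),
    class = "hex_grid"
  )
}

#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf("<hex_grid> pointy-top, side %.1f um, offset (%.2f, %.2f) um\n",
              x$side, x$offset[1L], x$offset[2L]))
  invisible(x)
}

#' Hexagon area of a grid
#' @param grid A [build_grid()] object or a side length in micrometers.
#' @return Area of one regular hexagon, `3*sqrt(3)/2 * side^2` (um^2).
#' @export
hex_area <- function(grid) {
  side <- if (inherits(grid, "hex_grid")) grid$side else grid
  3 * sqrt(3) / 2 * side^2
}

# Fractional axial coordinates of points, then cube rounding to the
# containing hexagon. Ties on hexagon boundaries resolve via the rounding
# rule (largest rounding error re-derived from the other two axes), which
# is deterministic.
axial_coords <- function(x, y, grid) {
  s <- grid$side
  xr <- x - grid$offset[1L]
  yr <- y - grid$offset[2L]
  qf <- (sqrt(3) / 3 * xr - yr / 3) / s
  rf <- (2 / 3 * yr) / s
  axial_round(qf, rf)
}

axial_round <- function(qf, rf) {
  xf <- qf
  zf <- rf
  yf <- -xf - zf
  rx <- round(xf)
  ry <- round(yf)
  rz <- round(zf)
  dx <- abs(rx - xf)
  dy <- abs(ry - yf)
  dz <- abs(rz - zf)
  i <- dx > dy & dx > dz
  rx[i] <- -ry[i] - rz[i]
  j <- !i & dy > dz
  # y is re-derived, not stored
  k <- !(i | j)
  rz[k] <- -rx[k] - ry[k]
  cbind(q = rx, r = rz)
}

#' Center of a hexagon in grid coordinates
#' @param q,r Integer axial coordinates.
#' @param grid A [build_grid()] object.
#' @return Two-column matrix of centers (um).
#' @export
hex_center <- function(q, r, grid) {
  s <- grid$side
  cbind(x = s * sqrt(3) * (q + r / 2) + grid$offset[1L],
        y = s * 1.5 * r + grid$offset[2L])
}

#' Assign cells to hexagons and aggregate marker counts
#'
#' Every compartment-filtered, marker-evaluated cell contributes to
#' exactly one hexagon's positive or negative count. Hexagons receiving
#' no cells are omitted.
#'
#' @param cellmap A [cell_map()].
#' @param grid A [build_grid()] object.
#' @param marker Binary marker name present in the cell map.
#' @param compartment Compartment whose cells are aggregated
#'   (default `"tumor"`).
#' @return A `hex_lattice`: data frame with columns `q`, `r`, `cx`, `cy`,
#'   `n_pos`, `n_neg`, `percent`, `retained` plus attributes `grid`,
#'   `marker`, `min_cells`.
#' @export
assign_cells <- function(cellmap, grid, marker, compartment = "tumor") {
  stopifnot(inherits(cellmap, "cell_map"), inherits(grid, "hex_grid"))
  if (!marker %in% names(cellmap$cells)) {
    stop("cell map has no marker column '", marker, "'")
  }
  cells <- compartment_cells(cellmap, compartment)
  flag <- cells[[marker]]
  keep <- !is.na(flag)
  cells <- cells[keep, , drop = FALSE]
  flag <- flag[keep]
  if (nrow(cells) == 0L) {
    lat <- data.frame(q = integer(), r = integer(), cx = numeric(), cy = numeric(),
                      n_pos = integer(), n_neg = integer(), percent = numeric(),
                      retained = logical())
  } else {
    ax <- axial_coords(cells$x, cells$y, grid)
    key <- paste(ax[, "q"], ax[, "r"])
    n_pos <- rowsum(as.integer(flag), key)
    n_tot <- rowsum(rep(1L, length(key)), key)
    first <- !duplicated(key)
    ord <- match(rownames(n_pos), key[first])
    q <- ax[first, "q"][ord]
    r <- ax[first, "r"][ord]
    ctr <- hex_center(q, r, grid)
    lat <- data.frame(q = as.integer(q), r = as.integer(r),
                      cx = ctr[, "x"], cy = ctr[, "y"],
                      n_pos = as.integer(n_pos[, 1L]),
                      n_neg = as.integer(n_tot[, 1L] - n_pos[, 1L]),
                      percent = 100 * n_pos[, 1L] / n_tot[, 1L],
                      retained = TRUE)
    lat <- lat[order(lat$r, lat$q), , drop = FALSE]
    rownames(lat) <- NULL
  }
  structure(lat, class = c("hex_lattice", "data.frame"),
            grid = grid, marker = marker, compartment = compartment,
            min_cells = NA_integer_)
}

#' Discard hexagons with insufficient sampling
#'
#' Marks hexagons with fewer than `min_cells` cells (positive + negative)
#' as not retained; they are excluded from all downstream statistics,
#' including the adjacency pairs of the co-occurrence matrix.
#'
#' @param lattice A `hex_lattice` from [assign_cells()].
#' @param min_cells Minimum cell count per hexagon (default 50).
#' @return The lattice with its `retained` flags updated.
#' @export
filter_hexes <- function(lattice, min_cells = 50) {
  stopifnot(inherits(lattice, "hex_lattice"))
  lattice$retained <- (lattice$n_pos + lattice$n_neg) >= min_cells
  attr(lattice, "min_cells") <- as.integer(min_cells)
  lattice
}

#' Adjacent pairs of retained hexagons
#'
#' All unordered pairs of retained hexagons at axial distance 1 (the
#' 6-neighborhood). Each pair appears once. Discarded hexagons do not
#' bridge adjacency.
#'
#' @param lattice A filtered `hex_lattice`.
#' @return Two-column integer matrix of row indices into `lattice`.
#' @export
neighbor_pairs <- function(lattice) {
  stopifnot(inherits(lattice, "hex_lattice"))
  idx <- which(lattice$retained)
  if (length(idx) < 2L) return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  q <- lattice$q[idx]
  r <- lattice$r[idx]
  key <- paste(q, r)
  lookup <- stats::setNames(idx, key)
  # half of the 6 axial directions, so each unordered pair is found once
  dirs <- rbind(c(1L, 0L), c(0L, 1L), c(-1L, 1L))
  out <- vector("list", nrow(dirs))
  for (d in seq_len(nrow(dirs))) {
    nb <- paste(q + dirs[d, 1L], r + dirs[d, 2L])
    hit <- !is.na(lookup[nb])
    out[[d]] <- cbind(i = idx[hit], j = unname(lookup[nb[hit]]))
  }
  pairs <- do.call(rbind, out)
  if (is.null(pairs)) pairs <- matrix(integer(), ncol = 2L)
  colnames(pairs) <- c("i", "j")
  pairs
}

#' Export per-hexagon records
#'
#' Debug/inspection export of one lattice as a data frame (optionally
#' written to CSV): case id, marker, axial coordinates, centers, counts,
#' percentage and retained flag.
#'
#' @param lattice A `hex_lattice`.
#' @param case_id Case identifier recorded in each row.
#' @param path Optional CSV output path.
#' @return The data frame, invisibly when `path` is given.
#' @export
hex_table <- function(lattice, case_id = "case", path = NULL) {
  stopifnot(inherits(lattice, "hex_lattice"))
  df <- data.frame(case_id = rep(case_id, nrow(lattice)),
                   marker = rep(attr(lattice, "marker"), nrow(lattice)),
                   q = lattice$q, r = lattice$r,
                   center_x_um = lattice$cx, center_y_um = lattice$cy,
                   n_pos = lattice$n_pos, n_neg = lattice$n_neg,
                   percent = lattice$percent, retained = lattice$retained)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
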