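#' Equal-area analysis grid
#'
#' The analysis lattice: square cells of `cell_size` meters on an equal-area
#' projected plane, so every cell covers the same ground area
#' (`(cell_size/1000)^2` km^2; 1 km^2 at the default 1000 m). The origin is
#' the upper-left corner of the extent; row indexes grow downward
#' (southward), column indexes grow to the right (eastward). The center of
#' cell (row i, col j), 1-based, is at
#' `(origin_x + (j - 0.5) * cell_size, origin_y - (i - 0.5) * cell_size)`.
#'
#' @param extent Numeric `c(xmin, ymin, xmax, ymax)` in projected meters.
#' @param cell_size Cell edge in meters (default 1000, i.e. 1 km^2 cells).
#' @param crs Grid CRS: `"behrmann"` or `"planar"`.
#' @return An object of class `ea_grid`.
#' @examples
#' g <- build_grid(c(0, 0, 10000, 10000))
#' g$n_rows # 10
#' @export
build_grid <- function(extent, cell_size = 1000, crs = "planar") {
  stopifnot(is.numeric(extent), length(extent) == 4L, all(is.finite(extent)))
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("cell_size must be a positive number of meters")
  }
  crs <- check_crs(crs, "grid CRS")
  if (crs == "longlat") stop("grid CRS must be projected and equal-area")
  names(extent) <- c("xmin", "ymin", "xmax", "ymax")
  width <- extent["xmax"] - extent["xmin"]
  height <- extent["ymax"] - extent["ymin"]
  if (width <= 0) stop("degenerate extent: width is ", width, " (xmax <= xmin)")
  if (height <= 0) stop("degenerate extent: height is ", height, " (ymax <= ymin)")
  structure(list(
    crs = crs,
    origin_x = unname(extent["xmin"]),
    origin_y = unname(extent["ymax"]),
    cell_size = cell_size,
    n_rows = as.integer(ceiling(height / cell_size - 1e-9)),
    n_cols = as.integer(ceiling(width / cell_size - 1e-9))
  ), class = "ea_grid")
}

#' @export
print.ea_grid <- function(x, ...) {
  cat(sprintf("<ea_grid: %d x %d cells of %g m (%s), origin (%.6g, %.6g)>\n",
              x$n_rows, x$n_cols, x$cell_size, x$crs, x$origin_x, x$origin_y))
  invisible(x)
}

#' Cell areas and centers
#'
#' @param grid An `ea_grid`.
#' @return `cell_area_km2`: area of one cell in km^2. `cell_centers_x` /
#'   `cell_centers_y`: center coordinates per column / per row.
#' @export
cell_area_km2 <- function(grid) (grid$cell_size / 1000)^2

#' @rdname cell_area_km2
#' @export
cell_centers_x <- function(grid) {
  grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
}

#' @rdname cell_area_km2
#' @export
cell_centers_y <- function(grid) {
  grid$origin_y - (seq_len(grid$n_rows) - 0.5) * grid$cell_size
}

grids_identical <- function(a, b) {
  for (f in c("crs", "origin_x", "origin_y", "cell_size", "n_rows", "n_cols")) {
    if (!isTRUE(all.equal(a[[f]], b[[f]]))) return(f)
  }
  TRUE
}

check_same_grid <- function(a, b) {
  mism <- grids_identical(a, b)
  if (!isTRUE(mism)) {
    stop("rasters are on different grids: parameter '", mism, "' differs")
  }
  invisible(TRUE)
}
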