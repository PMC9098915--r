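# Raster persistence: ESRI ASCII grid (.asc), a plain-text georeferenced
# raster format readable by standard GIS tools. The .asc header carries the
# grid georeferencing; the grid CRS name goes in a small JSON sidecar
# (<file>.meta.json) since the format itself has no CRS slot.

write_asc_matrix <- function(cells, grid, path, nodata = -9999L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$n_cols),
    paste("nrows", grid$n_rows),
    paste("xllcorner", format(grid$origin_x, digits = 15)),
    paste("yllcorner", format(grid$origin_y - grid$n_rows * grid$cell_size,
                              digits = 15)),
    paste("cellsize", format(grid$cell_size, digits = 15)),
    paste("NODATA_value", nodata)
  ), con)
  utils::write.table(cells, con, row.names = FALSE, col.names = FALSE)
  meta <- sub("\\.asc$", ".meta.json", path)
  if (identical(meta, path)) meta <- paste0(path, ".meta.json")
  jsonlite::write_json(list(crs = grid$crs), meta, auto_unbox = TRUE)
  invisible(path)
}

read_asc_matrix <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  cells <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(cells) <- NULL
  meta <- sub("\\.asc$", ".meta.json", path)
  if (identical(meta, path)) meta <- paste0(path, ".meta.json")
  crs <- if (file.exists(meta)) jsonlite::read_json(meta)$crs else "planar"
  grid <- structure(list(
    crs = crs,
    origin_x = unname(h["xllcorner"]),
    origin_y = unname(h["yllcorner"] + h["nrows"] * h["cellsize"]),
    cell_size = unname(h["cellsize"]),
    n_rows = as.integer(h["nrows"]),
    n_cols = as.integer(h["ncols"])
  ), class = "ea_grid")
  list(grid = grid, cells = cells)
}

#' Read and write presence rasters
#'
#' Presence rasters are stored as single-band ESRI ASCII grids with values
#' 0/1 and a JSON sidecar recording the CRS name.
#'
#' @param x A `presence_raster`.
#' @param path Output/input `.asc` path.
#' @return `write_presence_raster` returns `path` invisibly;
#'   `read_presence_raster` returns a `presence_raster`.
#' @export
write_presence_raster <- function(x, path) {
  stopifnot(inherits(x, "presence_raster"))
  write_asc_matrix(x$cells, x$grid, path)
}

#' @rdname write_presence_raster
#' @export
read_presence_raster <- function(path) {
  r <- read_asc_matrix(path)
  storage.mode(r$cells) <- "integer"
  presence_raster(r$grid, r$cells)
}
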