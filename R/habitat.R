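# Habitat layer preparation. A habitat layer is presence-only: geometries
# (polygons, or points carrying an optional reported area) under one habitat
# name. Each layer becomes one presence raster; its protected companion is
# the intersection with the merged PCA raster.

#' Build a habitat layer
#'
#' @param name Habitat identifier (e.g. `"warm-water corals"`).
#' @param geometry List of geometry objects (points and/or polygons).
#' @param reported_area_km2 Per-feature reported area in km^2 for points;
#'   `NA` (or 0, read as "no area assigned") falls back to the layer
#'   default at rasterization time. Ignored for polygons.
#' @param crs CRS of the geometries.
#' @return An object of class `habitat_layer`.
#' @export
habitat_layer <- function(name, geometry, reported_area_km2 = NA_real_,
                          crs = "planar") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.list(geometry))
  lapply(geometry, function(g) stopifnot(inherits(g, "hp_geom")))
  structure(list(
    name = name,
    geometry = geometry,
    reported_area_km2 = rep_len(as.numeric(reported_area_km2),
                                length(geometry)),
    crs = check_crs(crs)
  ), class = "habitat_layer")
}

#' @export
print.habitat_layer <- function(x, ...) {
  kinds <- vapply(x$geometry, function(g) g$kind, character(1))
  cat(sprintf("<habitat_layer '%s': %d features (%d polygon, %d point), crs %s>\n",
              x$name, length(x$geometry), sum(kinds == "polygon"),
              sum(kinds == "point"), x$crs))
  invisible(x)
}

#' Rasterize a habitat layer
#'
#' Points are buffered to their reported area — or to
#' `default_point_area_km2` (1 km^2 by default) when no area is assigned,
#' with a reported area of 0 treated as unassigned — then all geometries are
#' projected to the grid CRS, rasterized with the centroid rule and merged
#' with logical OR into a single presence raster for the habitat.
#'
#' @param layer A [habitat_layer()].
#' @param grid An `ea_grid`.
#' @param default_point_area_km2 Fallback buffered area for points without a
#'   reported area (must be > 0).
#' @return A `presence_raster` with a `"log"` attribute listing structurally
#'   invalid feature indexes that were skipped.
#' @export
prepare_habitat_raster <- function(layer, grid, default_point_area_km2 = 1) {
  stopifnot(inherits(layer, "habitat_layer"), inherits(grid, "ea_grid"),
            default_point_area_km2 > 0)
  polys <- list()
  invalid <- integer(0)
  for (k in seq_along(layer$geometry)) {
    g <- layer$geometry[[k]]
    ok <- geom_validate(g)
    if (!isTRUE(ok)) { invalid <- c(invalid, k); next }
    g <- to_equal_area(g, layer$crs, grid$crs)
    if (is_point(g)) {
      a <- layer$reported_area_km2[k]
      if (is.na(a) || a <= 0) a <- default_point_area_km2
      g <- buffer_point_to_area(g, a)
    }
    polys[[length(polys) + 1L]] <- g
  }
  if (length(polys) == 0L) {
    warning("habitat layer '", layer$name, "' has no valid features; ",
            "raster is empty")
  }
  out <- rasterize_centroid(polys, grid)
  attr(out, "log") <- list(habitat = layer$name,
                           n_features = length(layer$geometry),
                           invalid_feature_idx = invalid)
  out
}

#' Habitat-within-PCA raster
#'
#' The protected companion of a habitat raster: cell-wise AND with the
#' merged PCA raster.
#'
#' @param habitat,pca `presence_raster` objects on the identical grid.
#' @return A `presence_raster`; its pixel count never exceeds the habitat's.
#' @export
protected_habitat_raster <- function(habitat, pca) intersect_and(habitat, pca)

#' Union two habitat layers into one
#'
#' Concatenates the features of two layers (e.g. a knolls product and a
#' seamounts product) under a new name; rasterizing the union equals the OR
#' of the two inputs' rasters.
#'
#' @param a,b [habitat_layer()] objects on the same CRS.
#' @param name Name of the combined layer.
#' @return A `habitat_layer`.
#' @export
union_base_layers <- function(a, b, name) {
  stopifnot(inherits(a, "habitat_layer"), inherits(b, "habitat_layer"))
  if (!identical(a$crs, b$crs)) stop("layers have different CRS: ",
                                     a$crs, " vs ", b$crs)
  habitat_layer(name, c(a$geometry, b$geometry),
                c(a$reported_area_km2, b$reported_area_km2), crs = a$crs)
}
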