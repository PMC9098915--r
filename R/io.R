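# Vector layer I/O. GeoJSON is the supported interchange format (parsed
# with jsonlite). Geometries map onto the package's planar geometry types;
# MultiPolygons flatten to multi-ring polygons, which the even-odd
# containment rule handles without special casing. Real-world GeoJSON is
# lon/lat by convention; synthetic worlds record their planar CRS in a
# top-level "crs" name member which the reader honors.

geojson_to_geom <- function(g) {
  type <- g$type
  if (is.null(type)) stop("geometry without a 'type' member")
  if (type == "Point") {
    xy <- unlist(g$coordinates)
    return(hp_point(xy[1], xy[2]))
  }
  if (type == "Polygon") {
    rings <- lapply(g$coordinates, function(r) {
      do.call(rbind, lapply(r, function(p) unlist(p)[1:2]))
    })
    return(hp_polygon(rings))
  }
  if (type == "MultiPolygon") {
    rings <- unlist(lapply(g$coordinates, function(poly) {
      lapply(poly, function(r) do.call(rbind, lapply(r, function(p) unlist(p)[1:2])))
    }), recursive = FALSE)
    return(hp_polygon(rings))
  }
  stop("unsupported GeoJSON geometry type: ", type)
}

geom_to_geojson <- function(g) {
  if (is_point(g)) {
    list(type = "Point", coordinates = c(g$xy[1], g$xy[2]))
  } else {
    list(type = "Polygon", coordinates = lapply(g$rings, function(r) {
      r <- rbind(r, r[1, , drop = FALSE])   # close the ring
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    }))
  }
}

#' Read a vector layer
#'
#' Auto-detects the format by extension. GeoJSON (`.geojson` / `.json`) is
#' supported; GeoPackage and ESRI Shapefile are recognized but not readable
#' here (no OGR driver is available to this package) and raise a clear
#' error asking for a GeoJSON export.
#'
#' @param path Input file.
#' @param default_crs CRS assumed when the file declares none
#'   (`"longlat"`, the GeoJSON convention).
#' @return A list: `geometry` (list of geometry objects), `properties`
#'   (data frame, one row per feature), `crs`.
#' @export
read_vector_layer <- function(path, default_crs = "longlat") {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gpkg", "shp")) {
    stop("format '.", ext, "' is not readable by this package ",
         "(no OGR driver available); export the layer as GeoJSON")
  }
  if (!ext %in% c("geojson", "json")) {
    stop("unrecognized vector format '.", ext, "'; supported: .geojson/.json")
  }
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection in ", path)
  }
  crs <- default_crs
  if (!is.null(fc$crs$properties$name)) crs <- fc$crs$properties$name
  geometry <- lapply(fc$features, function(f) geojson_to_geom(f$geometry))
  props <- lapply(fc$features, function(f) {
    p <- f$properties
    lapply(p, function(v) if (is.null(v)) NA else v)
  })
  keys <- unique(unlist(lapply(props, names)))
  if (length(keys) == 0L) {
    properties <- as.data.frame(matrix(nrow = length(geometry), ncol = 0L))
  } else {
    properties <- as.data.frame(
      stats::setNames(lapply(keys, function(k) {
        vals <- lapply(props, function(p) {
          v <- if (k %in% names(p)) p[[k]] else NA
          if (is.null(v) || length(v) != 1L) NA else v
        })
        unlist(vals, use.names = FALSE)
      }), keys),
      stringsAsFactors = FALSE, optional = TRUE)
  }
  list(geometry = geometry, properties = properties, crs = check_crs(crs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a vector layer as GeoJSON
#'
#' @param geometry List of geometry objects.
#' @param properties Data frame of per-feature attributes (or `NULL`).
#' @param path Output `.geojson` path.
#' @param crs CRS name recorded in the file.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(geometry, properties = NULL, path, crs = "planar") {
  n <- length(geometry)
  features <- lapply(seq_len(n), function(i) {
    props <- if (is.null(properties)) stats::setNames(list(), character(0)) else {
      as.list(properties[i, , drop = FALSE])
    }
    list(type = "Feature", properties = props,
         geometry = geom_to_geojson(geometry[[i]]))
  })
  fc <- list(type = "FeatureCollection",
             crs = list(type = "name", properties = list(name = crs)),
             features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Load PCA records from a vector file
#'
#' Applies a configurable attribute-name map (WDPA-style defaults: `STATUS`,
#' `DESIG_ENG`, `REP_AREA`, id `WDPAID`) so real database extracts load
#' without code changes.
#'
#' @param path GeoJSON file of PCA features.
#' @param attr_map Named character vector mapping roles `id`, `status`,
#'   `designation`, `rep_area` to attribute names in the file.
#' @param source `"protected_area"` or `"oecm"`.
#' @param default_crs CRS assumed when the file declares none.
#' @return A [pca_records()] collection.
#' @export
read_pca_file <- function(path,
                          attr_map = c(id = "WDPAID", status = "STATUS",
                                       designation = "DESIG_ENG",
                                       rep_area = "REP_AREA"),
                          source = "protected_area",
                          default_crs = "longlat") {
  lay <- read_vector_layer(path, default_crs)
  p <- lay$properties
  get_col <- function(role, default) {
    nm <- attr_map[[role]]
    if (!is.null(nm) && nm %in% names(p)) p[[nm]] else default
  }
  n <- length(lay$geometry)
  ids <- get_col("id", NULL)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  pca_records(
    id = as.character(ids),
    geometry = lay$geometry,
    status = as.character(get_col("status", rep(NA_character_, n))),
    designation = as.character(get_col("designation", rep(NA_character_, n))),
    reported_area_km2 = as.numeric(get_col("rep_area", rep(NA_real_, n))),
    source = source,
    crs = lay$crs
  )
}

#' Load a habitat layer from one or more vector files
#'
#' Multiple files for one habitat (e.g. a polygon product and a point
#' product) are merged into a single layer.
#'
#' @param paths GeoJSON file(s) for the habitat.
#' @param name Habitat name.
#' @param area_attr Attribute carrying a per-feature reported area (km^2).
#' @param default_crs CRS assumed when a file declares none.
#' @return A [habitat_layer()].
#' @export
read_habitat_files <- function(paths, name, area_attr = "REP_AREA_KM2",
                               default_crs = "longlat") {
  geoms <- list(); areas <- numeric(0); crs <- NULL
  for (path in paths) {
    lay <- read_vector_layer(path, default_crs)
    if (is.null(crs)) crs <- lay$crs
    if (!identical(crs, lay$crs)) {
      stop("habitat '", name, "': files disagree on CRS (", crs, " vs ",
           lay$crs, ")")
    }
    a <- if (area_attr %in% names(lay$properties)) {
      as.numeric(lay$properties[[area_attr]])
    } else rep(NA_real_, length(lay$geometry))
    geoms <- c(geoms, lay$geometry)
    areas <- c(areas, a)
  }
  habitat_layer(name, geoms, areas, crs = crs %||% default_crs)
}

#' Load jurisdiction zones from a vector file
#'
#' @param path GeoJSON file with one feature per jurisdiction.
#' @param attr_map Named character vector mapping roles `zone_id`,
#'   `landlocked`, `disputed`, `joint_regime` to attribute names.
#' @param default_crs CRS assumed when the file declares none.
#' @return A data frame suitable for [build_zoneset()], with the layer CRS
#'   in attribute `crs`.
#' @export
read_zones_file <- function(path,
                            attr_map = c(zone_id = "ISO_TER1",
                                         landlocked = "LANDLOCKED",
                                         disputed = "DISPUTED",
                                         joint_regime = "JOINT_REGIME"),
                            default_crs = "longlat") {
  lay <- read_vector_layer(path, default_crs)
  p <- lay$properties
  n <- length(lay$geometry)
  get_flag <- function(role) {
    nm <- attr_map[[role]]
    if (!is.null(nm) && nm %in% names(p)) {
      v <- p[[nm]]
      !is.na(v) & (v == TRUE | v == 1 | toupper(as.character(v)) == "TRUE")
    } else rep(FALSE, n)
  }
  idnm <- attr_map[["zone_id"]]
  if (is.null(idnm) || !idnm %in% names(p)) {
    stop("zones file lacks the zone id attribute '", idnm, "'")
  }
  out <- data.frame(zone_id = as.character(p[[idnm]]),
                    landlocked = get_flag("landlocked"),
                    disputed = get_flag("disputed"),
                    joint_regime = get_flag("joint_regime"),
                    stringsAsFactors = FALSE)
  out$geometry <- lay$geometry
  attr(out, "crs") <- lay$crs
  out
}
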