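# Coordinate reference handling. Two projected CRS are understood:
#   "planar"    - an already-projected equal-area plane in meters (synthetic
#                 worlds); projection is the identity.
#   "behrmann"  - cylindrical equal-area on the WGS84 ellipsoid, standard
#                 parallels +/-30 deg, central meridian 0. Equal-area by
#                 construction, so every 1 km grid cell covers 1 km^2.
# Geographic input is declared as "longlat" (WGS84 degrees).

WGS84_A  <- 6378137
WGS84_E2 <- 0.0066943799901413165

# Snyder's q auxiliary for the equal-area latitude: q(phi) integrates the
# ellipsoidal area element, making x = a*k0*lambda, y = a*q/(2*k0) exactly
# area-preserving.
cea_q <- function(phi) {
  e <- sqrt(WGS84_E2)
  s <- sin(phi)
  (1 - WGS84_E2) * (s / (1 - WGS84_E2 * s^2) -
                    (1 / (2 * e)) * log((1 - e * s) / (1 + e * s)))
}

behrmann_k0 <- function() {
  phi_s <- 30 * pi / 180
  cos(phi_s) / sqrt(1 - WGS84_E2 * sin(phi_s)^2)
}

# Forward Behrmann projection of lon/lat degrees -> meters.
behrmann_forward <- function(lon, lat) {
  k0 <- behrmann_k0()
  lam <- lon * pi / 180
  phi <- lat * pi / 180
  cbind(WGS84_A * k0 * lam, WGS84_A * cea_q(phi) / (2 * k0))
}

known_crs <- c("planar", "behrmann", "longlat")

check_crs <- function(crs, what = "CRS") {
  if (is.null(crs) || !is.character(crs) || length(crs) != 1L || is.na(crs)) {
    stop(what, " must be one of: ", paste(known_crs, collapse = ", "))
  }
  crs <- tolower(crs)
  if (!crs %in% known_crs) {
    stop("unknown ", what, " '", crs, "'; supported: ",
         paste(known_crs, collapse = ", "))
  }
  crs
}

#' Project a geometry onto the analysis equal-area plane
#'
#' Reprojects from `source_crs` to `target_crs`. Identity when the two match
#' (both already-projected CRS are in meters). Geographic input
#' (`"longlat"`, WGS84 degrees) is projected with the Behrmann cylindrical
#' equal-area projection; polygon edges are densified in lon/lat first so
#' long graticule-straight edges keep their area through the projection.
#'
#' @param geom A geometry object (point or polygon).
#' @param source_crs CRS of the input: `"longlat"`, `"behrmann"` or `"planar"`.
#' @param target_crs CRS of the analysis grid: `"behrmann"` or `"planar"`.
#' @param densify_deg Maximum lon/lat edge length (degrees) before
#'   projection; ignored for projected input.
#' @return The geometry in `target_crs` meters.
#' @export
to_equal_area <- function(geom, source_crs, target_crs, densify_deg = 0.05) {
  source_crs <- check_crs(source_crs, "source CRS")
  target_crs <- check_crs(target_crs, "target CRS")
  if (target_crs == "longlat") stop("target CRS must be projected")
  ok <- geom_validate(geom)
  if (!isTRUE(ok)) stop("invalid geometry: ", ok)
  if (source_crs == target_crs) return(geom)
  if (source_crs != "longlat") {
    stop("cannot transform between projected CRS '", source_crs, "' and '",
         target_crs, "'; re-export the layer in lon/lat or the grid CRS")
  }
  if (target_crs != "behrmann") {
    stop("geographic input requires the 'behrmann' grid CRS, not 'planar'")
  }
  if (is_point(geom)) {
    xy <- behrmann_forward(geom$xy[1], geom$xy[2])
    return(hp_point(xy[1], xy[2]))
  }
  rings <- lapply(geom$rings, function(r) {
    r <- densify_ring(r, densify_deg)
    behrmann_forward(r[, 1], r[, 2])
  })
  hp_polygon(rings)
}
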