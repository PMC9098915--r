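# Jurisdiction zones and zonal pixel statistics. Zones are the union of a
# territory's land and its EEZ; landlocked, disputed and joint-regime areas
# are filtered out before analysis. Cells of the ocean assigned to no
# jurisdiction form the ABNJ (areas beyond national jurisdiction) zone.

#' Build the zone set
#'
#' Drops flagged jurisdictions (landlocked / disputed / joint-regime),
#' rasterizes the remaining zone polygons onto the grid (centroid rule), and
#' derives the ABNJ remainder: ocean cells assigned to no jurisdiction.
#' Where zone polygons overlap, a cell is assigned to the zone earliest in
#' the stable sort of `zone_id`; conflicts are counted in the log.
#'
#' @param jurisdictions A data frame with columns `zone_id` (unique),
#'   `geometry` (list of polygon geometries), and optional logical columns
#'   `landlocked`, `disputed`, `joint_regime` (default `FALSE`).
#' @param ocean A polygon geometry for the ocean outline, or `NULL` to omit
#'   the ABNJ zone.
#' @param grid An `ea_grid`.
#' @param crs CRS of the input geometries.
#' @return An object of class `zone_set`: `zones` (data frame `zone_id`,
#'   `kind`), `zone_raster` (integer matrix, 0 = unassigned, k = index into
#'   `zones`), `grid`, and a `log` with dropped zones and overlap counts.
#' @export
build_zoneset <- function(jurisdictions, ocean, grid, crs = "planar") {
  stopifnot(is.data.frame(jurisdictions), inherits(grid, "ea_grid"))
  crs <- check_crs(crs)
  if (anyDuplicated(jurisdictions$zone_id)) {
    stop("duplicate zone_id: ",
         paste(unique(jurisdictions$zone_id[duplicated(jurisdictions$zone_id)]),
               collapse = ", "))
  }
  for (flag in c("landlocked", "disputed", "joint_regime")) {
    if (is.null(jurisdictions[[flag]])) jurisdictions[[flag]] <- FALSE
  }
  flagged <- jurisdictions$landlocked | jurisdictions$disputed |
    jurisdictions$joint_regime
  dropped <- jurisdictions$zone_id[flagged]
  keep <- jurisdictions[!flagged, , drop = FALSE]
  keep <- keep[order(keep$zone_id), , drop = FALSE]

  zone_raster <- matrix(0L, grid$n_rows, grid$n_cols)
  n_conflict <- 0L
  for (k in seq_len(nrow(keep))) {
    g <- to_equal_area(keep$geometry[[k]], crs, grid$crs)
    r <- rasterize_centroid(g, grid)
    new_cells <- r$cells == 1L
    n_conflict <- n_conflict + sum(new_cells & zone_raster != 0L)
    assign_cells <- new_cells & zone_raster == 0L
    zone_raster[assign_cells] <- k
  }
  zones <- data.frame(zone_id = keep$zone_id,
                      kind = rep("jurisdiction", nrow(keep)),
                      stringsAsFactors = FALSE)

  if (is.null(ocean) || (is_polygon(ocean) && geom_area(ocean) == 0)) {
    warning("empty ocean geometry; ABNJ zone omitted")
  } else {
    ocean_r <- rasterize_centroid(to_equal_area(ocean, crs, grid$crs), grid)
    abnj_cells <- ocean_r$cells == 1L & zone_raster == 0L
    if (any(abnj_cells)) {
      zones <- rbind(zones, data.frame(zone_id = "ABNJ", kind = "abnj",
                                       stringsAsFactors = FALSE))
      zone_raster[abnj_cells] <- nrow(zones)
    }
  }
  structure(list(
    zones = zones,
    zone_raster = zone_raster,
    grid = grid,
    log = list(dropped_zones = dropped, overlap_cells = n_conflict)
  ), class = "zone_set")
}

#' @export
print.zone_set <- function(x, ...) {
  cat(sprintf("<zone_set: %d zones (%s), %d assigned cells on %d x %d grid>\n",
              nrow(x$zones),
              paste(utils::head(x$zones$zone_id, 5), collapse = ", "),
              sum(x$zone_raster != 0L), x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

#' Per-zone habitat and protected-habitat pixel counts
#'
#' For every (zone, habitat) pair: `E` = habitat pixels whose cell is
#' assigned to the zone, `P` = protected-habitat pixels likewise. Rows with
#' `E = 0` are retained and flagged absent. The per-habitat global extent
#' `E_glob` is the sum of `E` over all zones in the table (ABNJ included);
#' habitat pixels on cells assigned to no zone are excluded from every
#' denominator and reported in the log.
#'
#' @param habitat_rasters Named list of habitat `presence_raster`s.
#' @param protected_rasters Named list of the matching protected rasters
#'   (same names).
#' @param zoneset A [build_zoneset()] result on the same grid.
#' @return A data frame of class `count_table` with columns `zone_id`,
#'   `habitat`, `E`, `P`, `present`; attributes `E_glob` (named vector) and
#'   `log` (unassigned pixel counts per habitat).
#' @export
zonal_counts <- function(habitat_rasters, protected_rasters, zoneset) {
  stopifnot(inherits(zoneset, "zone_set"), length(habitat_rasters) >= 1L)
  habs <- names(habitat_rasters)
  stopifnot(!is.null(habs), all(nzchar(habs)))
  missing_prot <- setdiff(habs, names(protected_rasters))
  if (length(missing_prot) > 0) {
    stop("habitat(s) missing a protected companion raster: ",
         paste(missing_prot, collapse = ", "))
  }
  nz <- nrow(zoneset$zones)
  zr <- zoneset$zone_raster
  rows <- vector("list", length(habs))
  unassigned <- stats::setNames(integer(length(habs)), habs)
  for (h in seq_along(habs)) {
    hr <- habitat_rasters[[habs[h]]]
    pr <- protected_rasters[[habs[h]]]
    check_same_grid(zoneset$grid, hr$grid)
    check_same_grid(zoneset$grid, pr$grid)
    if (any(pr$cells > hr$cells)) {
      stop("protected raster exceeds habitat raster for '", habs[h], "'")
    }
    E <- tabulate(zr[hr$cells == 1L], nbins = nz)
    P <- tabulate(zr[pr$cells == 1L], nbins = nz)
    unassigned[h] <- sum(hr$cells == 1L & zr == 0L)
    rows[[h]] <- data.frame(zone_id = zoneset$zones$zone_id,
                            habitat = habs[h], E = E, P = P,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$zone_id, out$habitat), , drop = FALSE]
  rownames(out) <- NULL
  out$present <- out$E > 0L
  attr(out, "E_glob") <- tapply(out$E, out$habitat, sum)[habs]
  attr(out, "log") <- list(unassigned_habitat_pixels = unassigned)
  class(out) <- c("count_table", class(out))
  out
}
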