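# Shared fixtures, built in code.

# Brute-force centroid rasterization oracle: classify every cell center of
# the whole grid with mgcv::in.out (an independent point-in-polygon
# implementation), OR-ed over polygons. Boundary behaviour of mgcv is
# unspecified, so oracle comparisons use polygons whose edges avoid cell
# centers (random vertices almost surely do).
brute_force_raster <- function(polygons, grid) {
  if (inherits(polygons, "hp_geom")) polygons <- list(polygons)
  cx <- cell_centers_x(grid)
  cy <- cell_centers_y(grid)
  pts <- cbind(rep(cx, each = grid$n_rows), rep(cy, times = grid$n_cols))
  occ <- rep(FALSE, nrow(pts))
  for (g in polygons) {
    bnd <- do.call(rbind, lapply(g$rings, function(r) rbind(r, c(NA, NA))))
    bnd <- bnd[-nrow(bnd), , drop = FALSE]
    occ <- occ | mgcv::in.out(bnd, pts)
  }
  presence_raster(grid, matrix(as.integer(occ), grid$n_rows, grid$n_cols))
}

# A raster from an explicit set of (row, col) cells.
raster_from_cells <- function(grid, rows, cols) {
  m <- matrix(0L, grid$n_rows, grid$n_cols)
  if (length(rows)) m[cbind(rows, cols)] <- 1L
  presence_raster(grid, m)
}

# Random star-shaped polygon of a given approximate size, for fuzzing.
random_star_polygon <- function(cx, cy, radius, nv = sample(5:20, 1)) {
  theta <- sort(runif(nv, 0, 2 * pi))
  rad <- runif(nv, 0.3, 1) * radius
  hp_polygon(cbind(cx + rad * cos(theta), cy + rad * sin(theta)))
}

# Random valid count tables for index-identity fuzzing.
random_count_table <- function(n_zones = 5, n_habitats = 4) {
  zones <- sprintf("Z%02d", seq_len(n_zones))
  habs <- sprintf("h%02d", seq_len(n_habitats))
  df <- expand.grid(zone_id = zones, habitat = habs,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$E <- rpois(nrow(df), 80) * rbinom(nrow(df), 1, 0.8)
  df$P <- vapply(df$E, function(e) if (e == 0) 0L else
    as.integer(sample(0:e, 1)), integer(1))
  df
}

# Tiny synthetic world used by several suites (fast but full-featured).
small_world_spec <- function(seed = 1L, ...) {
  synth_world_spec(seed = seed, world_km = c(300, 300), n_jurisdictions = 3L,
                   n_habitats = 2L, n_patches = 5L,
                   patch_area_km2 = c(40, 250), ...)
}
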