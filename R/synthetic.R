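# Synthetic worlds with analytically known ground truth. The generator
# emulates the three real inputs (PCA records, habitat layers, jurisdiction
# zones + ocean) on a planar equal-area CRS, with protection fractions that
# are exact by construction: each habitat feature's protected part is a
# half-plane clip of the feature itself, so vector areas need no sampling.
#
# Layout conventions (fixed, documented):
#   * the ocean is the full rectangle [0, W] x [0, H] meters;
#   * jurisdictions are vertical strips tiling the bottom half (y < H/2);
#   * the top half is beyond national jurisdiction (the ABNJ remainder);
#   * habitat patches (rectangles, or points buffered to circles) are placed
#     pairwise disjoint across ALL habitats, wholly inside one zone, so
#     exact areas are additive and zone membership is unambiguous.

#' Specify a synthetic world
#'
#' @param seed Integer RNG seed; a fixed seed reproduces the world exactly.
#' @param world_km `c(width, height)` of the ocean rectangle in km.
#' @param n_jurisdictions Number of jurisdiction strips (>= 1).
#' @param n_habitats Number of habitat layers.
#' @param n_patches Habitat patches per (zone, habitat), ABNJ included.
#' @param patch_area_km2 `c(min, max)` patch area; areas are drawn
#'   log-uniformly over this range.
#' @param point_fraction Share of features emitted as point-with-reported-
#'   area instead of polygons.
#' @param protection Matrix of target protection fractions `p[j, h]` in
#'   `[0, 1]`, rows = jurisdictions then ABNJ, columns = habitats. Default:
#'   the levels 0, 0.25, 0.5, 0.75, 1 cycled over (zone, habitat) pairs.
#' @param decoys Append filter-matching decoy PCA records (Proposed /
#'   Not Reported / MAB / point-without-area) covering whole zones, which
#'   must not change any index once filtering works.
#' @param oecm_fraction Share of valid PCA records labelled as OECMs (both
#'   sources travel the same preparation path).
#' @return A list of class `synth_world_spec`.
#' @export
synth_world_spec <- function(seed = 1L,
                             world_km = c(900, 900),
                             n_jurisdictions = 6L,
                             n_habitats = 3L,
                             n_patches = 10L,
                             patch_area_km2 = c(50, 500),
                             point_fraction = 0.25,
                             protection = NULL,
                             decoys = TRUE,
                             oecm_fraction = 0.25) {
  n_zones <- n_jurisdictions + 1L  # + ABNJ
  if (is.null(protection)) {
    levels <- c(0, 0.25, 0.5, 0.75, 1)
    protection <- matrix(levels[(seq_len(n_zones * n_habitats) - 1L) %% 5L + 1L],
                         nrow = n_zones, ncol = n_habitats)
  }
  protection <- as.matrix(protection)
  stopifnot(
    length(world_km) == 2L, all(world_km > 0),
    n_jurisdictions >= 1L, n_habitats >= 1L, n_patches >= 1L,
    length(patch_area_km2) == 2L, all(patch_area_km2 > 0),
    patch_area_km2[2] >= patch_area_km2[1],
    point_fraction >= 0, point_fraction <= 1,
    identical(dim(protection), c(n_zones, as.integer(n_habitats))) ||
      identical(dim(protection), as.integer(c(n_zones, n_habitats))),
    all(protection >= 0 & protection <= 1),
    oecm_fraction >= 0, oecm_fraction <= 1
  )
  structure(list(
    seed = as.integer(seed), world_km = world_km,
    n_jurisdictions = as.integer(n_jurisdictions),
    n_habitats = as.integer(n_habitats),
    n_patches = as.integer(n_patches),
    patch_area_km2 = patch_area_km2,
    point_fraction = point_fraction,
    protection = protection,
    decoys = isTRUE(decoys),
    oecm_fraction = oecm_fraction
  ), class = "synth_world_spec")
}

runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

# Place a w x h (meters) bbox uniformly inside `region` (xmin,ymin,xmax,ymax)
# avoiding `occupied` bboxes (list of length-4 vectors) with a gap; NULL when
# it cannot be placed.
place_bbox <- function(w, h, region, occupied, gap = 1000, max_tries = 300L) {
  xr <- c(region[1] + gap, region[3] - gap - w)
  yr <- c(region[2] + gap, region[4] - gap - h)
  if (xr[2] <= xr[1] || yr[2] <= yr[1]) return(NULL)
  for (t in seq_len(max_tries)) {
    x0 <- stats::runif(1, xr[1], xr[2])
    y0 <- stats::runif(1, yr[1], yr[2])
    bb <- c(x0 - gap, y0 - gap, x0 + w + gap, y0 + h + gap)
    clash <- FALSE
    for (o in occupied) {
      if (bb[1] < o[3] && o[1] < bb[3] && bb[2] < o[4] && o[2] < bb[4]) {
        clash <- TRUE; break
      }
    }
    if (!clash) return(c(x0, y0, x0 + w, y0 + h))
  }
  NULL
}

# Carve the sub-polygon on one side of a straight cut line (direction
# `angle`) holding exactly `fraction` of the polygon's area (uniroot on the
# cut offset). A randomized angle keeps the cut oblique to the raster grid,
# so centroid-rule quantization errors along the cut average out across
# rows instead of accumulating.
carve_fraction <- function(poly, fraction, angle = 0) {
  stopifnot(fraction > 0, fraction < 1)
  total <- geom_area(poly)
  a <- cos(angle); b <- sin(angle)
  verts <- do.call(rbind, poly$rings)
  proj <- a * verts[, 1] + b * verts[, 2]
  f <- function(cc) {
    part <- clip_halfplane(poly, a, b, cc)
    (if (is.null(part)) 0 else geom_area(part)) - fraction * total
  }
  cc <- stats::uniroot(f, range(proj), tol = 1e-7)$root
  clip_halfplane(poly, a, b, cc)
}

#' Generate a synthetic world
#'
#' Builds jurisdiction zones, an ocean outline, habitat layers, PCA records
#' and the exact ground truth implied by the construction (vector areas, no
#' rasters). See [synth_world_spec()] for the knobs.
#'
#' @param spec A [synth_world_spec()].
#' @return A list of class `synth_world`: `jurisdictions` (data frame for
#'   [build_zoneset()]), `ocean`, `habitats` (named list of
#'   [habitat_layer()]), `pca` ([pca_records()]), `ground_truth` (data frame
#'   `zone_id`, `habitat`, `extent_km2`, `protected_km2`, `p_target`),
#'   `decoy_ids`, `extent` (grid extent in meters), `spec`.
#' @export
generate_world <- function(spec) {
  stopifnot(inherits(spec, "synth_world_spec"))
  set.seed(spec$seed)
  W <- spec$world_km[1] * 1000
  H <- spec$world_km[2] * 1000
  ocean <- hp_rect(0, 0, W, H)
  nj <- spec$n_jurisdictions
  strip_w <- W / nj
  zone_ids <- sprintf("Z%02d", seq_len(nj))
  zone_regions <- lapply(seq_len(nj), function(j) {
    c((j - 1) * strip_w, 0, j * strip_w, H / 2)
  })
  jurisdictions <- data.frame(zone_id = zone_ids, landlocked = FALSE,
                              disputed = FALSE, joint_regime = FALSE,
                              stringsAsFactors = FALSE)
  jurisdictions$geometry <- lapply(zone_regions, function(r) {
    hp_rect(r[1], r[2], r[3], r[4])
  })
  all_ids <- c(zone_ids, "ABNJ")
  regions <- c(zone_regions, list(c(0, H / 2, W, H)))
  hab_names <- sprintf("habitat_%02d", seq_len(spec$n_habitats))

  occupied <- list()
  hab_geoms <- lapply(hab_names, function(h) list())
  hab_areas <- lapply(hab_names, function(h) numeric(0))
  names(hab_geoms) <- names(hab_areas) <- hab_names
  pca_geoms <- list(); pca_area <- numeric(0)
  gt <- expand.grid(zone_id = all_ids, habitat = hab_names,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gt$extent_km2 <- 0; gt$protected_km2 <- 0
  gt$p_target <- spec$protection[cbind(match(gt$zone_id, all_ids),
                                       match(gt$habitat, hab_names))]

  for (j in seq_along(all_ids)) {
    for (h in seq_along(hab_names)) {
      p <- spec$protection[j, h]
      for (k in seq_len(spec$n_patches)) {
        A <- runif_log(1, spec$patch_area_km2[1], spec$patch_area_km2[2])
        as_point <- stats::runif(1) < spec$point_fraction
        if (as_point) {
          r <- sqrt(A * 1e6 / pi) * 1.01  # bbox pad beyond the exact-area n-gon
          bb <- place_bbox(2 * r, 2 * r, regions[[j]], occupied)
          if (is.null(bb)) {
            stop("infeasible synthetic spec: cannot place a ", round(A, 1),
                 " km2 patch in zone ", all_ids[j],
                 " (reduce n_patches or patch areas)")
          }
          center <- hp_point((bb[1] + bb[3]) / 2, (bb[2] + bb[4]) / 2)
          poly <- buffer_point_to_area(center, A)
          feat_geom <- center
        } else {
          # randomly rotated rectangle: decorrelates patch edges and the
          # protection cut line from the grid axes, so pixel-quantization
          # errors average out across rows instead of adding up
          aspect <- stats::runif(1, 0.5, 2)
          w <- sqrt(A * 1e6 * aspect); hh <- A * 1e6 / w
          ang <- stats::runif(1, 0, pi / 2)
          corners <- cbind(c(-w, w, w, -w) / 2, c(-hh, -hh, hh, hh) / 2)
          rot <- corners %*% rbind(c(cos(ang), sin(ang)),
                                   c(-sin(ang), cos(ang)))
          bw <- diff(range(rot[, 1])); bh <- diff(range(rot[, 2]))
          bb <- place_bbox(bw, bh, regions[[j]], occupied)
          if (is.null(bb)) {
            stop("infeasible synthetic spec: cannot place a ", round(A, 1),
                 " km2 patch in zone ", all_ids[j],
                 " (reduce n_patches or patch areas)")
          }
          cx <- (bb[1] + bb[3]) / 2; cy <- (bb[2] + bb[4]) / 2
          poly <- hp_polygon(cbind(rot[, 1] + cx, rot[, 2] + cy))
          feat_geom <- poly
        }
        occupied[[length(occupied) + 1L]] <- bb
        hab_geoms[[h]] <- c(hab_geoms[[h]], list(feat_geom))
        hab_areas[[h]] <- c(hab_areas[[h]], if (as_point) A else NA_real_)
        row <- which(gt$zone_id == all_ids[j] & gt$habitat == hab_names[h])
        gt$extent_km2[row] <- gt$extent_km2[row] + A
        if (p > 0) {
          pca_poly <- if (p >= 1) poly else
            carve_fraction(poly, p, angle = stats::runif(1, 0, pi))
          pca_geoms[[length(pca_geoms) + 1L]] <- pca_poly
          prot_km2 <- geom_area(pca_poly) / 1e6
          pca_area <- c(pca_area, prot_km2)
          gt$protected_km2[row] <- gt$protected_km2[row] + prot_km2
        }
      }
    }
  }

  n_pca <- length(pca_geoms)
  src <- ifelse(stats::runif(n_pca) < spec$oecm_fraction,
                "oecm", "protected_area")
  ids <- sprintf("PCA_%04d", seq_len(n_pca))
  status <- rep("Designated", n_pca)
  desig <- rep("Marine Reserve", n_pca)
  area <- rep(NA_real_, n_pca)
  decoy_ids <- character(0)
  if (spec$decoys) {
    # whole-zone cover polygons that would drive every index to 1 if the
    # cleaning rules failed to drop them, plus a point without an area
    for (j in seq_along(all_ids)) {
      r <- regions[[j]]
      zone_poly <- hp_rect(r[1], r[2], r[3], r[4])
      dd <- data.frame(
        status = c("Proposed", "Not Reported", "Designated", "Designated"),
        desig = c("Marine Reserve", "Marine Reserve",
                  "UNESCO Man and the Biosphere Reserve", "Marine Reserve"),
        point = c(FALSE, FALSE, FALSE, TRUE), stringsAsFactors = FALSE)
      for (q in seq_len(nrow(dd))) {
        id <- sprintf("DECOY_%s_%d", all_ids[j], q)
        decoy_ids <- c(decoy_ids, id)
        ids <- c(ids, id)
        status <- c(status, dd$status[q])
        desig <- c(desig, dd$desig[q])
        area <- c(area, NA_real_)
        src <- c(src, "protected_area")
        pca_geoms[[length(pca_geoms) + 1L]] <- if (dd$point[q]) {
          hp_point((r[1] + r[3]) / 2, (r[2] + r[4]) / 2)
        } else zone_poly
      }
    }
  }
  pca <- pca_records(id = ids, geometry = pca_geoms, status = status,
                     designation = desig, reported_area_km2 = area,
                     source = src, crs = "planar")
  habitats <- lapply(hab_names, function(h) {
    habitat_layer(h, hab_geoms[[h]], hab_areas[[h]], crs = "planar")
  })
  names(habitats) <- hab_names
  structure(list(
    jurisdictions = jurisdictions, ocean = ocean, habitats = habitats,
    pca = pca, ground_truth = gt, decoy_ids = decoy_ids,
    extent = c(0, 0, W, H), crs = "planar", spec = spec
  ), class = "synth_world")
}

#' @export
print.synth_world <- function(x, ...) {
  cat(sprintf(paste0("<synth_world: %g x %g km, %d jurisdictions + ABNJ, ",
                     "%d habitats, %d PCA records (%d decoys), seed %d>\n"),
              x$spec$world_km[1], x$spec$world_km[2], x$spec$n_jurisdictions,
              x$spec$n_habitats, nrow(x$pca), length(x$decoy_ids),
              x$spec$seed))
  invisible(x)
}

#' Exact vector-geometry oracle
#'
#' Recomputes per-(zone, habitat) extent and protected areas by exact
#' polygon clipping — no rasters. Habitat features (points buffered to
#' their exact-area circles) are intersected with each jurisdiction polygon
#' (Sutherland-Hodgman; zone polygons must be convex); the remainder of
#' each feature is attributed to ABNJ. Protected areas intersect features
#' with every PCA polygon that survives the filter rules; kept PCA polygons
#' are assumed convex and pairwise disjoint, which holds for generated
#' worlds.
#'
#' @param world A [generate_world()] result (or a list with the same
#'   `jurisdictions`, `habitats`, `pca` fields).
#' @param rules Filter rules applied to the PCA records.
#' @param default_point_area_km2 Buffered area for habitat points without a
#'   reported area.
#' @return A data frame `zone_id`, `habitat`, `extent_km2`, `protected_km2`.
#' @export
exact_oracle <- function(world, rules = filter_rules(),
                         default_point_area_km2 = 1) {
  zones <- world$jurisdictions
  flagged <- (zones$landlocked %||% FALSE) | (zones$disputed %||% FALSE) |
    (zones$joint_regime %||% FALSE)
  zones <- zones[!flagged, , drop = FALSE]
  zones <- zones[order(zones$zone_id), , drop = FALSE]
  kept <- filter_pca(world$pca, rules)$kept
  pca_polys <- lapply(seq_len(nrow(kept)), function(k) {
    g <- kept$geometry[[k]]
    ok <- geom_validate(g)
    if (!isTRUE(ok)) return(NULL)
    if (is_point(g)) buffer_point_to_area(g, kept$reported_area_km2[k]) else g
  })
  pca_polys <- Filter(Negate(is.null), pca_polys)

  rows <- list()
  for (hname in names(world$habitats)) {
    lay <- world$habitats[[hname]]
    ext <- stats::setNames(numeric(nrow(zones) + 1L),
                           c(zones$zone_id, "ABNJ"))
    prot <- ext
    for (k in seq_along(lay$geometry)) {
      g <- lay$geometry[[k]]
      if (!isTRUE(geom_validate(g))) next
      if (is_point(g)) {
        a <- lay$reported_area_km2[k]
        if (is.na(a) || a <= 0) a <- default_point_area_km2
        g <- buffer_point_to_area(g, a)
      }
      total <- geom_area(g) / 1e6
      in_zones <- 0
      for (z in seq_len(nrow(zones))) {
        az <- intersection_area_convex(g, zones$geometry[[z]]) / 1e6
        ext[z] <- ext[z] + az
        in_zones <- in_zones + az
      }
      ext["ABNJ"] <- ext["ABNJ"] + max(0, total - in_zones)
      for (pp in pca_polys) {
        inter <- clip_convex(g, pp)
        if (is.null(inter)) next
        ptotal <- geom_area(inter) / 1e6
        p_in_zones <- 0
        for (z in seq_len(nrow(zones))) {
          paz <- intersection_area_convex(inter, zones$geometry[[z]]) / 1e6
          prot[z] <- prot[z] + paz
          p_in_zones <- p_in_zones + paz
        }
        prot["ABNJ"] <- prot["ABNJ"] + max(0, ptotal - p_in_zones)
      }
    }
    rows[[hname]] <- data.frame(zone_id = names(ext), habitat = hname,
                                extent_km2 = as.numeric(ext),
                                protected_km2 = as.numeric(prot),
                                stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Indexes implied by exact areas
#'
#' Turns a ground-truth (or [exact_oracle()]) area table into the same
#' index quantities the raster pipeline reports, using vector areas as the
#' "counts".
#'
#' @param gt Data frame with `zone_id`, `habitat`, `extent_km2`,
#'   `protected_km2`.
#' @param tau Target fraction for the targeted score.
#' @return An `index_table` (see [aggregate_indexes()]).
#' @export
ground_truth_indexes <- function(gt, tau = 0.3) {
  counts <- data.frame(zone_id = gt$zone_id, habitat = gt$habitat,
                       E = gt$extent_km2, P = gt$protected_km2,
                       stringsAsFactors = FALSE)
  aggregate_indexes(per_habitat_ratios(counts), tau = tau)
}

#' Write a synthetic world to disk
#'
#' Emits the same vector formats the pipeline ingests — zones, ocean,
#' per-habitat layers and PCA records as GeoJSON (with the planar CRS
#' recorded in the file) — plus the ground truth as a CSV. The output
#' doubles as documentation of the expected input schema.
#'
#' @param world A [generate_world()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of files written, invisibly.
#' @export
write_world <- function(world, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create directory: ", dir)
  }
  files <- c(zones = file.path(dir, "zones.geojson"),
             ocean = file.path(dir, "ocean.geojson"),
             pca = file.path(dir, "pca.geojson"),
             ground_truth = file.path(dir, "ground_truth.csv"))
  zprops <- data.frame(ISO_TER1 = world$jurisdictions$zone_id,
                       LANDLOCKED = world$jurisdictions$landlocked,
                       DISPUTED = world$jurisdictions$disputed,
                       JOINT_REGIME = world$jurisdictions$joint_regime,
                       stringsAsFactors = FALSE)
  write_geojson(world$jurisdictions$geometry, zprops, files["zones"],
                crs = world$crs)
  write_geojson(list(world$ocean), NULL, files["ocean"], crs = world$crs)
  pprops <- data.frame(WDPAID = world$pca$id, STATUS = world$pca$status,
                       DESIG_ENG = world$pca$designation,
                       REP_AREA = world$pca$reported_area_km2,
                       SOURCE = world$pca$source, stringsAsFactors = FALSE)
  write_geojson(world$pca$geometry, pprops, files["pca"], crs = world$crs)
  for (h in names(world$habitats)) {
    lay <- world$habitats[[h]]
    f <- file.path(dir, paste0("habitat_", h, ".geojson"))
    files[paste0("habitat_", h)] <- f
    write_geojson(lay$geometry,
                  data.frame(REP_AREA_KM2 = lay$reported_area_km2,
                             stringsAsFactors = FALSE),
                  f, crs = lay$crs)
  }
  utils::write.csv(world$ground_truth, files["ground_truth"],
                   row.names = FALSE)
  invisible(files)
}

#' Random polygon collection for rasterization-fidelity checks
#'
#' Draws `n` star-shaped simple polygons with exact target areas (shoelace
#' area rescaled to the drawn log-uniform area), placed without overlap in
#' a square planar extent. Used to measure how closely centroid-rule pixel
#' counts track true vector areas.
#'
#' @param n Number of polygons.
#' @param area_km2 `c(min, max)` log-uniform area range.
#' @param extent_km Width/height of the square placement extent in km.
#' @param n_vertices `c(min, max)` vertices per polygon.
#' @return List with `polygons` (list of geometries), `areas_km2`,
#'   `extent` (meters).
#' @export
synth_polygon_collection <- function(n = 100L, area_km2 = c(4, 10000),
                                     extent_km = 2000,
                                     n_vertices = c(8L, 24L)) {
  ext <- c(0, 0, extent_km * 1000, extent_km * 1000)
  polys <- vector("list", n)
  areas <- runif_log(n, area_km2[1], area_km2[2])
  areas <- sort(areas, decreasing = TRUE)  # place big ones first
  occupied <- list()
  for (k in seq_len(n)) {
    nv <- sample(n_vertices[1]:n_vertices[2], 1L)
    theta <- sort(stats::runif(nv, 0, 2 * pi))
    rad <- stats::runif(nv, 0.3, 1)
    x <- rad * cos(theta); y <- rad * sin(theta)
    a0 <- abs(ring_signed_area(cbind(x, y)))
    s <- sqrt(areas[k] * 1e6 / a0)
    x <- x * s; y <- y * s
    w <- diff(range(x)); h <- diff(range(y))
    bb <- place_bbox(w, h, ext, occupied, gap = 1000)
    if (is.null(bb)) {
      stop("infeasible polygon collection: cannot place polygon ", k,
           " (extent too small for the requested areas)")
    }
    occupied[[length(occupied) + 1L]] <- bb
    polys[[k]] <- hp_polygon(cbind(x - min(x) + bb[1], y - min(y) + bb[2]))
  }
  list(polygons = polys, areas_km2 = areas, extent = ext)
}
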