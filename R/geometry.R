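# Lightweight planar geometry primitives used throughout the pipeline.
# Geometries are plain lists: points carry an (x, y) pair, polygons a list of
# rings (n x 2 coordinate matrices, not explicitly closed).  Multi-part
# polygons are represented as additional rings under even-odd semantics, so
# holes need no special casing anywhere downstream.

#' Create a point geometry
#'
#' @param x,y Coordinates in the layer's CRS.
#' @return A geometry object of kind `"point"`.
#' @export
hp_point <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == 1L, length(y) == 1L,
            is.finite(x), is.finite(y))
  structure(list(kind = "point", xy = c(x, y)), class = "hp_geom")
}

#' Create a polygon geometry
#'
#' Rings are interpreted with the even-odd rule: a location is inside the
#' polygon when it is covered by an odd number of rings. Holes are therefore
#' just additional rings; ring orientation does not matter for containment.
#'
#' @param rings A single n x 2 matrix or a list of such matrices. Rings may be
#'   given closed (first vertex repeated) or open; they are stored open.
#' @return A geometry object of kind `"polygon"`.
#' @export
hp_polygon <- function(rings) {
  if (is.matrix(rings)) rings <- list(rings)
  stopifnot(is.list(rings), length(rings) >= 1L)
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    storage.mode(r) <- "double"
    if (ncol(r) != 2L) stop("each ring must be an n x 2 coordinate matrix")
    n <- nrow(r)
    if (n >= 2L && isTRUE(all(r[1L, ] == r[n, ]))) r <- r[-n, , drop = FALSE]
    if (nrow(r) < 3L) stop("a ring needs at least 3 distinct vertices")
    if (!all(is.finite(r))) stop("ring coordinates must be finite")
    dimnames(r) <- NULL
    r
  })
  structure(list(kind = "polygon", rings = rings), class = "hp_geom")
}

#' Axis-aligned rectangle polygon
#'
#' @param xmin,ymin,xmax,ymax Rectangle bounds (projected units).
#' @return A polygon geometry.
#' @export
hp_rect <- function(xmin, ymin, xmax, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  hp_polygon(cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax)))
}

is_polygon <- function(g) inherits(g, "hp_geom") && g$kind == "polygon"
is_point   <- function(g) inherits(g, "hp_geom") && g$kind == "point"

#' @export
print.hp_geom <- function(x, ...) {
  if (x$kind == "point") {
    cat(sprintf("<point (%.6g, %.6g)>\n", x$xy[1], x$xy[2]))
  } else {
    nv <- sum(vapply(x$rings, nrow, integer(1)))
    cat(sprintf("<polygon: %d ring(s), %d vertices, area %.6g>\n",
                length(x$rings), nv, geom_area(x)))
  }
  invisible(x)
}

ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' Planar polygon area (shoelace formula)
#'
#' Sums the signed areas of all rings and returns the absolute value, so a
#' hole ring wound opposite to its shell subtracts correctly.
#'
#' @param geom A polygon geometry.
#' @return Area in squared coordinate units.
#' @export
geom_area <- function(geom) {
  stopifnot(is_polygon(geom))
  abs(sum(vapply(geom$rings, ring_signed_area, numeric(1))))
}

geom_bbox <- function(geom) {
  if (is_point(geom)) {
    c(xmin = geom$xy[1], ymin = geom$xy[2], xmax = geom$xy[1], ymax = geom$xy[2])
  } else {
    xy <- do.call(rbind, geom$rings)
    c(xmin = min(xy[, 1]), ymin = min(xy[, 2]),
      xmax = max(xy[, 1]), ymax = max(xy[, 2]))
  }
}

#' Structural geometry validation
#'
#' Checks ring structure (>= 3 vertices, finite coordinates, nonzero area).
#' Self-intersecting rings are accepted: all containment tests in this
#' package use the even-odd rule, which is well defined for them.
#'
#' @param geom A geometry object.
#' @return `TRUE` if valid, otherwise a character reason.
#' @export
geom_validate <- function(geom) {
  if (!inherits(geom, "hp_geom")) return("not a geometry object")
  if (is_point(geom)) {
    if (!all(is.finite(geom$xy))) return("non-finite point coordinates")
    return(TRUE)
  }
  if (geom_area(geom) <= 0) return("zero-area polygon")
  TRUE
}

#' Even-odd point-in-polygon test
#'
#' Vectorized containment test used by the centroid-rule rasterizer.
#' `boundary_inside = TRUE` implements the documented tie-break: a query
#' point lying exactly on a ring edge counts as inside.
#'
#' @param px,py Query point coordinates (equal-length vectors).
#' @param geom A polygon geometry.
#' @param boundary_inside Count on-boundary points as inside.
#' @return Logical vector, one element per query point.
#' @export
points_in_polygon <- function(px, py, geom, boundary_inside = TRUE) {
  stopifnot(is_polygon(geom))
  inside <- logical(length(px))
  onb <- logical(length(px))
  for (ring in geom$rings) {
    n <- nrow(ring)
    x1 <- ring[, 1]; y1 <- ring[, 2]
    x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
    scale <- max(abs(range(ring)), 1)
    eps <- 1e-9 * scale
    for (k in seq_len(n)) {
      a1 <- x1[k]; b1 <- y1[k]; a2 <- x2[k]; b2 <- y2[k]
      crosses <- (b1 > py) != (b2 > py)
      if (any(crosses)) {
        xint <- a1 + (py[crosses] - b1) / (b2 - b1) * (a2 - a1)
        flip <- px[crosses] < xint
        idx <- which(crosses)[flip]
        inside[idx] <- !inside[idx]
      }
      if (boundary_inside) {
        dx <- a2 - a1; dy <- b2 - b1
        len <- sqrt(dx * dx + dy * dy)
        if (len > 0) {
          cross <- abs((px - a1) * dy - (py - b1) * dx) / len
          t <- ((px - a1) * dx + (py - b1) * dy) / (len * len)
          onb <- onb | (cross <= eps & t >= -eps & t <= 1 + eps)
        }
      }
    }
  }
  if (boundary_inside) inside | onb else inside
}

# Clip a single ring against the half-plane a*x + b*y <= c
# (Sutherland-Hodgman step). Returns an open ring matrix or NULL when empty.
clip_ring_halfplane <- function(ring, a, b, c) {
  n <- nrow(ring)
  vx <- ring[, 1]; vy <- ring[, 2]
  d <- a * vx + b * vy - c
  out_x <- numeric(0); out_y <- numeric(0)
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    in1 <- d[k] <= 0; in2 <- d[k2] <= 0
    if (in1) { out_x <- c(out_x, vx[k]); out_y <- c(out_y, vy[k]) }
    if (in1 != in2) {
      t <- d[k] / (d[k] - d[k2])
      out_x <- c(out_x, vx[k] + t * (vx[k2] - vx[k]))
      out_y <- c(out_y, vy[k] + t * (vy[k2] - vy[k]))
    }
  }
  if (length(out_x) < 3L) return(NULL)
  # drop consecutive duplicate vertices created by on-line input points
  n_out <- length(out_x)
  keep <- c(TRUE, abs(diff(out_x)) > 0 | abs(diff(out_y)) > 0)
  if (out_x[n_out] == out_x[1] && out_y[n_out] == out_y[1]) keep[n_out] <- FALSE
  out_x <- out_x[keep]; out_y <- out_y[keep]
  if (length(out_x) < 3L) return(NULL)
  ring <- cbind(out_x, out_y, deparse.level = 0)
  if (abs(ring_signed_area(ring)) == 0) return(NULL)
  ring
}

#' Clip a polygon by a half-plane
#'
#' Keeps the part of the polygon with `a*x + b*y <= c`. Intended for simple
#' (single-ring) polygons; each ring is clipped independently.
#'
#' @param geom A polygon geometry.
#' @param a,b,c Half-plane coefficients, keeping `a*x + b*y <= c`.
#' @return A polygon geometry, or `NULL` when nothing remains.
#' @export
clip_halfplane <- function(geom, a, b, c) {
  stopifnot(is_polygon(geom))
  rings <- Filter(Negate(is.null),
                  lapply(geom$rings, clip_ring_halfplane, a = a, b = b, c = c))
  if (length(rings) == 0L) return(NULL)
  hp_polygon(rings)
}

#' Clip a polygon by a convex polygon
#'
#' Sutherland-Hodgman clipping: the subject polygon is clipped successively
#' by each edge of the convex clip polygon. The clip polygon must be convex
#' and single-ring; the subject may be any simple polygon.
#'
#' @param geom Subject polygon geometry.
#' @param convex Convex single-ring polygon geometry.
#' @return Clipped polygon geometry, or `NULL` when the intersection is empty.
#' @export
clip_convex <- function(geom, convex) {
  stopifnot(is_polygon(geom), is_polygon(convex), length(convex$rings) == 1L)
  ring <- convex$rings[[1]]
  if (ring_signed_area(ring) < 0) ring <- ring[rev(seq_len(nrow(ring))), ]
  out <- geom
  n <- nrow(ring)
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    # CCW edge (p1 -> p2): interior satisfies cross(p2-p1, q-p1) >= 0,
    # i.e. -dy*x + dx*y <= -dy*x1 + dx*y1 ... rearranged below.
    dx <- ring[k2, 1] - ring[k, 1]; dy <- ring[k2, 2] - ring[k, 2]
    a <- dy; b <- -dx; c <- dy * ring[k, 1] - dx * ring[k, 2]
    out <- clip_halfplane(out, a, b, c)
    if (is.null(out)) return(NULL)
  }
  out
}

#' Intersection area of a polygon with a convex polygon
#'
#' @param geom Subject polygon.
#' @param convex Convex single-ring clip polygon.
#' @return Area of the intersection (0 when empty).
#' @export
intersection_area_convex <- function(geom, convex) {
  clipped <- clip_convex(geom, convex)
  if (is.null(clipped)) 0 else geom_area(clipped)
}

#' Buffer a point to a circular polygon of exact area
#'
#' Builds a regular polygon approximating a circle around a projected point.
#' The vertex radius is inflated so the *polygon* area equals the requested
#' area exactly (a regular n-gon inscribed in the circle of radius
#' sqrt(A/pi) would undershoot by ~(2*pi/n)^2/6).
#'
#' @param point A point geometry in projected meters.
#' @param area_km2 Target polygon area in square kilometres (> 0).
#' @param n_vertices Number of polygon vertices (>= 128 by default).
#' @return A polygon geometry whose shoelace area is `area_km2` (in m^2).
#' @export
buffer_point_to_area <- function(point, area_km2, n_vertices = 128L) {
  stopifnot(is_point(point))
  if (!is.numeric(area_km2) || length(area_km2) != 1L || !is.finite(area_km2) ||
      area_km2 <= 0) {
    stop("area_km2 must be a positive number, got: ", format(area_km2))
  }
  n <- max(as.integer(n_vertices), 8L)
  area_m2 <- area_km2 * 1e6
  # regular n-gon with vertex radius r has area n*r^2*sin(2*pi/n)/2
  r <- sqrt(2 * area_m2 / (n * sin(2 * pi / n)))
  theta <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  hp_polygon(cbind(point$xy[1] + r * cos(theta), point$xy[2] + r * sin(theta)))
}

# Densify each ring edge so no segment exceeds max_step (used before
# reprojection so straight lon/lat edges stay area-faithful).
densify_ring <- function(ring, max_step) {
  n <- nrow(ring)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    p1 <- ring[k, ]; p2 <- ring[k2, ]
    steps <- max(1L, ceiling(sqrt(sum((p2 - p1)^2)) / max_step))
    t <- seq(0, 1, length.out = steps + 1L)[-(steps + 1L)]
    out[[k]] <- cbind(p1[1] + t * (p2[1] - p1[1]), p1[2] + t * (p2[2] - p1[2]))
  }
  do.call(rbind, out)
}
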