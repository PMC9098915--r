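# Protected/conserved-area (PCA) record preparation: the cleaning rules
# applied to WDPA/WD-OECM-style records before rasterization. Records are a
# data frame with a geometry list-column plus the attributes the rules need.

#' Build a PCA record collection
#'
#' @param id Character vector of unique record identifiers.
#' @param geometry List of geometry objects ([hp_point()] / [hp_polygon()]).
#' @param status Status text (e.g. `"Designated"`, `"Proposed"`,
#'   `"Not Reported"`); `NA` is treated downstream as `"Not Reported"`.
#' @param designation Free-text designation (used for MAB detection).
#' @param reported_area_km2 Reported area in km^2 (`NA` when not reported).
#' @param source `"protected_area"` or `"oecm"`.
#' @param crs CRS of the geometries.
#' @return A data frame of class `pca_records` with a `crs` attribute.
#' @export
pca_records <- function(id, geometry, status,
                        designation = NA_character_,
                        reported_area_km2 = NA_real_,
                        source = "protected_area",
                        crs = "planar") {
  n <- length(id)
  stopifnot(length(geometry) == n, !anyDuplicated(id))
  lapply(geometry, function(g) stopifnot(inherits(g, "hp_geom")))
  src <- rep_len(as.character(source), n)
  stopifnot(all(src %in% c("protected_area", "oecm")))
  area <- rep_len(as.numeric(reported_area_km2), n)
  if (any(!is.na(area) & area < 0)) stop("reported_area_km2 must be >= 0")
  df <- data.frame(
    id = as.character(id),
    status = rep_len(as.character(status), n),
    designation = rep_len(as.character(designation), n),
    reported_area_km2 = area,
    source = src,
    stringsAsFactors = FALSE
  )
  df$geometry <- geometry
  df$geometry_kind <- vapply(geometry, function(g) g$kind, character(1))
  attr(df, "crs") <- check_crs(crs)
  class(df) <- c("pca_records", class(df))
  df
}

#' PCA filter rules
#'
#' Default profile mirrors standard protected-area coverage practice:
#' UNESCO Man and the Biosphere (MAB) reserves are excluded, as are records
#' with status `"Proposed"` or `"Not Reported"` and point records without a
#' reported area. Missing status counts as `"Not Reported"`.
#'
#' @param excluded_statuses Statuses to drop (exact, case-sensitive match).
#' @param mab_pattern Regular expression matched case-insensitively against
#'   the designation text; the default catches both "Man and Biosphere" and
#'   "Man and the Biosphere" phrasings.
#' @param drop_points_without_area Drop point records lacking a positive
#'   reported area.
#' @return A list of class `filter_rules`.
#' @export
filter_rules <- function(excluded_statuses = c("Proposed", "Not Reported"),
                         mab_pattern = "Man and( the)? Biosphere",
                         drop_points_without_area = TRUE) {
  stopifnot(length(excluded_statuses) >= 1L)
  structure(list(
    excluded_statuses = as.character(excluded_statuses),
    mab_pattern = mab_pattern,
    drop_points_without_area = isTRUE(drop_points_without_area)
  ), class = "filter_rules")
}

#' Filter PCA records
#'
#' Applies the rules in a fixed order — MAB designation, then excluded
#' status, then point-without-area — so each dropped record carries exactly
#' one primary reason. The kept and dropped sets partition the input.
#'
#' @param records A `pca_records` collection.
#' @param rules A [filter_rules()] object.
#' @return A list with `kept` (a `pca_records` subset) and `dropped` (a data
#'   frame of `id`, `reason` with reasons `"mab"`, `"status"`,
#'   `"point_without_area"`).
#' @export
filter_pca <- function(records, rules = filter_rules()) {
  stopifnot(inherits(records, "pca_records"), inherits(rules, "filter_rules"))
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  if (n > 0) {
    desig <- ifelse(is.na(records$designation), "", records$designation)
    is_mab <- grepl(rules$mab_pattern, desig, ignore.case = TRUE)
    status <- ifelse(is.na(records$status), "Not Reported", records$status)
    bad_status <- status %in% rules$excluded_statuses
    no_area <- is.na(records$reported_area_km2) | records$reported_area_km2 <= 0
    pt_no_area <- rules$drop_points_without_area &
      records$geometry_kind == "point" & no_area
    reason[pt_no_area] <- "point_without_area"
    reason[bad_status] <- "status"
    reason[is_mab] <- "mab"
  }
  keep <- is.na(reason)
  kept <- records[keep, , drop = FALSE]
  attr(kept, "crs") <- attr(records, "crs")
  class(kept) <- class(records)
  list(
    kept = kept,
    dropped = data.frame(id = records$id[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE)
  )
}

# Project one record geometry to the grid CRS and, for points, buffer to the
# reported area. Returns a polygon, or NULL (with a log entry) when the
# geometry fails structural validation.
record_to_polygon <- function(geom, kind, area_km2, source_crs, grid_crs) {
  ok <- geom_validate(geom)
  if (!isTRUE(ok)) return(structure(list(), invalid = ok))
  g <- to_equal_area(geom, source_crs, grid_crs)
  if (kind == "point") buffer_point_to_area(g, area_km2) else g
}

#' Prepare the merged PCA presence raster
#'
#' The full PCA preparation path: filter records, buffer surviving points to
#' their reported area (planar circles in grid meters), project everything
#' to the grid CRS, rasterize with the centroid rule, and merge all layers
#' with logical OR (overlaps never double-count). Protected-area and OECM
#' records travel the same path.
#'
#' @param records A `pca_records` collection.
#' @param rules A [filter_rules()] object.
#' @param grid An `ea_grid`.
#' @return A `presence_raster` with a `"log"` attribute: counts kept/dropped
#'   per reason, ids of structurally invalid geometries, and the dropped
#'   audit table.
#' @export
prepare_pca_raster <- function(records, rules = filter_rules(), grid) {
  stopifnot(inherits(grid, "ea_grid"))
  f <- filter_pca(records, rules)
  src_crs <- attr(records, "crs")
  polys <- list()
  invalid <- character(0)
  for (k in seq_len(nrow(f$kept))) {
    p <- record_to_polygon(f$kept$geometry[[k]], f$kept$geometry_kind[k],
                           f$kept$reported_area_km2[k], src_crs, grid$crs)
    if (!is.null(attr(p, "invalid"))) {
      invalid <- c(invalid, f$kept$id[k])
    } else {
      polys[[length(polys) + 1L]] <- p
    }
  }
  if (length(polys) == 0L) {
    warning("no valid PCA records remain after filtering; raster is empty")
  }
  out <- rasterize_centroid(polys, grid)
  drop_counts <- table(factor(f$dropped$reason,
                              levels = c("mab", "status", "point_without_area")))
  attr(out, "log") <- list(
    n_input = nrow(records),
    n_kept = nrow(f$kept) - length(invalid),
    dropped_by_reason = stats::setNames(as.integer(drop_counts),
                                        names(drop_counts)),
    invalid_geometry_ids = invalid,
    dropped = f$dropped
  )
  out
}

#' Write a filter audit log
#'
#' One row per input record: id, action (kept/dropped), reason.
#'
#' @param filtered Result of [filter_pca()].
#' @param path Output path (tab-delimited text).
#' @return `path`, invisibly.
#' @export
write_audit_log <- function(filtered, path) {
  audit <- rbind(
    if (nrow(filtered$kept) > 0)
      data.frame(id = filtered$kept$id, action = "kept", reason = "",
                 stringsAsFactors = FALSE),
    if (nrow(filtered$dropped) > 0)
      data.frame(id = filtered$dropped$id, action = "dropped",
                 reason = filtered$dropped$reason, stringsAsFactors = FALSE)
  )
  utils::write.table(audit, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
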