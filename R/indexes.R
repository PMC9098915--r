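# Index calculations. Per (zone, habitat): lphpi = P/E (local protected
# proportion), gphpi = P/E_glob (contribution to global protection), and the
# targeted score gphpi - tau * E/E_glob, positive exactly when the zone
# protects more than the fraction tau of its habitat. Zone-level indexes
# average the per-habitat values over habitats present in the zone.

#' Per-habitat protection ratios
#'
#' Computes, for every (zone, habitat) row of a count table, the local
#' proportion protected `lphpi = P / E` and the global-contribution
#' proportion `gphpi = P / E_glob`. Rows where the habitat is absent from
#' the zone (`E = 0`) keep `NA` ratios — absence is not zero protection.
#' Habitats with zero global extent cannot be normalized and are dropped
#' with a warning.
#'
#' @param counts A [zonal_counts()] `count_table` (or any data frame with
#'   `zone_id`, `habitat`, `E`, `P` and an `E_glob` attribute; when the
#'   attribute is missing, `E_glob` is recomputed as the per-habitat column
#'   sum of `E`).
#' @return A data frame `zone_id`, `habitat`, `E`, `P`, `E_glob`, `lphpi`,
#'   `gphpi`.
#' @export
per_habitat_ratios <- function(counts) {
  stopifnot(all(c("zone_id", "habitat", "E", "P") %in% names(counts)))
  if (any(counts$P > counts$E) || any(counts$P < 0)) {
    stop("invalid counts: need 0 <= P <= E in every row")
  }
  e_glob <- attr(counts, "E_glob")
  if (is.null(e_glob)) e_glob <- tapply(counts$E, counts$habitat, sum)
  out <- data.frame(zone_id = counts$zone_id, habitat = counts$habitat,
                    E = counts$E, P = counts$P,
                    E_glob = as.numeric(e_glob[counts$habitat]),
                    stringsAsFactors = FALSE)
  empty <- unique(out$habitat[out$E_glob == 0])
  if (length(empty) > 0) {
    warning("habitat(s) with zero global extent dropped: ",
            paste(empty, collapse = ", "))
    out <- out[!out$habitat %in% empty, , drop = FALSE]
  }
  out$lphpi <- ifelse(out$E > 0, out$P / out$E, NA_real_)
  out$gphpi <- ifelse(out$E > 0, out$P / out$E_glob, NA_real_)
  rownames(out) <- NULL
  out
}

#' Aggregate zone-level indexes
#'
#' Adds the per-habitat targeted score
#' `targeted = gphpi - tau * E / E_glob` and averages `lphpi`, `gphpi` and
#' `targeted` per zone over the habitats present there (`E > 0`); absent
#' habitats contribute to no average. Zones where no habitat is present are
#' excluded. The default is the unweighted arithmetic mean; an extent-
#' weighted mean (weights `E`) is available as an option.
#'
#' @param ratios Output of [per_habitat_ratios()].
#' @param tau Target protected fraction in (0, 1); default 0.3, the 30%
#'   coverage target.
#' @param weighted Use extent-weighted means instead of unweighted.
#' @return A data frame of class `index_table`: `zone_id`, `n_habitats`,
#'   `LPHPI`, `GPHPI`, `targeted`, with attributes `tau` and `per_habitat`
#'   (the ratios table augmented with the per-habitat `targeted` column).
#' @export
aggregate_indexes <- function(ratios, tau = 0.3, weighted = FALSE) {
  stopifnot(is.numeric(tau), length(tau) == 1L, tau > 0, tau < 1)
  ratios$targeted <- ifelse(ratios$E > 0,
                            ratios$gphpi - tau * ratios$E / ratios$E_glob,
                            NA_real_)
  pres <- ratios[ratios$E > 0, , drop = FALSE]
  if (nrow(pres) == 0L) {
    out <- data.frame(zone_id = character(0), n_habitats = integer(0),
                      LPHPI = numeric(0), GPHPI = numeric(0),
                      targeted = numeric(0), stringsAsFactors = FALSE)
  } else {
    zsplit <- split(pres, pres$zone_id)
    avg <- function(v, w) if (weighted) sum(v * w) / sum(w) else mean(v)
    out <- do.call(rbind, lapply(zsplit, function(d) {
      data.frame(zone_id = d$zone_id[1], n_habitats = nrow(d),
                 LPHPI = avg(d$lphpi, d$E), GPHPI = avg(d$gphpi, d$E),
                 targeted = avg(d$targeted, d$E), stringsAsFactors = FALSE)
    }))
    out <- out[order(out$zone_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "tau") <- tau
  attr(out, "per_habitat") <- ratios
  class(out) <- c("index_table", class(out))
  out
}

#' @export
print.index_table <- function(x, digits = 4, ...) {
  cat(sprintf("Habitat protection indexes (tau = %g, %d zones)\n",
              attr(x, "tau"), nrow(x)))
  print.data.frame(x, digits = digits, row.names = FALSE, ...)
  invisible(x)
}

#' Global per-habitat summary
#'
#' Totals computed from the full rasters, independent of the areas of
#' interest: per habitat, the total and protected pixel counts and their
#' split between jurisdiction-assigned cells and everything beyond national
#' jurisdiction (the ABNJ zone plus any unassigned cells), with the
#' resulting proportions. The two components always sum to the totals.
#'
#' @param habitat_rasters,protected_rasters Named lists of
#'   `presence_raster`s (matching names).
#' @param zoneset A [build_zoneset()] result on the same grid.
#' @return A data frame: `habitat`, `total_px`, `protected_px`,
#'   `jurisdiction_px`, `abnj_px`, `jurisdiction_protected_px`,
#'   `abnj_protected_px`, `prop_protected`, `prop_extent_abnj`.
#' @export
global_summary <- function(habitat_rasters, protected_rasters, zoneset) {
  stopifnot(inherits(zoneset, "zone_set"))
  jur_idx <- which(zoneset$zones$kind == "jurisdiction")
  jur_cells <- matrix(zoneset$zone_raster %in% jur_idx,
                      nrow(zoneset$zone_raster))
  rows <- lapply(names(habitat_rasters), function(h) {
    hr <- habitat_rasters[[h]]; pr <- protected_rasters[[h]]
    check_same_grid(zoneset$grid, hr$grid)
    tot <- sum(hr$cells); prot <- sum(pr$cells)
    jur <- sum(hr$cells == 1L & jur_cells)
    jur_p <- sum(pr$cells == 1L & jur_cells)
    data.frame(habitat = h, total_px = tot, protected_px = prot,
               jurisdiction_px = jur, abnj_px = tot - jur,
               jurisdiction_protected_px = jur_p,
               abnj_protected_px = prot - jur_p,
               prop_protected = if (tot > 0) prot / tot else NA_real_,
               prop_extent_abnj = if (tot > 0) (tot - jur) / tot else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

metadata_header <- function(metadata) {
  if (length(metadata) == 0L) return(character(0))
  paste0("# ", names(metadata), ": ",
         vapply(metadata, function(v) paste(format(v), collapse = " "),
                character(1)))
}

write_csv_with_header <- function(df, path, metadata) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(metadata_header(metadata), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the index output tables
#'
#' Writes four UTF-8 comma-delimited tables with a fixed column order and a
#' `#`-prefixed run-metadata header: averaged indexes per zone
#' (`zone_indexes.csv`), per-habitat indexes per zone
#' (`zone_habitat_indexes.csv`), habitat-specific targeted results
#' (`zone_habitat_targeted.csv`), and the global summary
#' (`global_summary.csv`).
#'
#' @param index_table An [aggregate_indexes()] result.
#' @param ratios The matching [per_habitat_ratios()] table (the
#'   `per_habitat` attribute of `index_table` is used when `NULL`).
#' @param summary A [global_summary()] table (optional).
#' @param path Output directory (created if needed).
#' @param metadata Named list written into each file header (e.g. grid
#'   parameters, tau, input digests).
#' @return Character vector of files written, invisibly.
#' @export
write_index_tables <- function(index_table, ratios = NULL, summary = NULL,
                               path, metadata = list()) {
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE)) {
    stop("cannot create output directory: ", path)
  }
  if (is.null(ratios)) ratios <- attr(index_table, "per_habitat")
  metadata <- c(list(tau = attr(index_table, "tau")), metadata)
  files <- character(0)

  zi <- as.data.frame(index_table)[, c("zone_id", "n_habitats", "LPHPI",
                                       "GPHPI", "targeted"), drop = FALSE]
  f <- file.path(path, "zone_indexes.csv")
  write_csv_with_header(zi, f, metadata); files <- c(files, f)

  if (!is.null(ratios)) {
    zh <- ratios[, c("zone_id", "habitat", "E", "P", "E_glob",
                     "lphpi", "gphpi"), drop = FALSE]
    f <- file.path(path, "zone_habitat_indexes.csv")
    write_csv_with_header(zh, f, metadata); files <- c(files, f)
    if (!is.null(ratios$targeted)) {
      zt <- ratios[, c("zone_id", "habitat", "gphpi", "targeted"),
                   drop = FALSE]
      f <- file.path(path, "zone_habitat_targeted.csv")
      write_csv_with_header(zt, f, metadata); files <- c(files, f)
    }
  }
  if (!is.null(summary)) {
    f <- file.path(path, "global_summary.csv")
    write_csv_with_header(summary, f, metadata); files <- c(files, f)
  }
  invisible(files)
}

#' Read back a written index table
#'
#' @param path A CSV written by [write_index_tables()].
#' @return The data frame, with the `#` metadata header skipped.
#' @export
read_index_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
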