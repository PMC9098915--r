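# End-to-end orchestration from a single YAML config: prepare-pca ->
# prepare-habitats -> zones -> counts -> indexes. Every stage writes its
# artifact plus a manifest (input digests + parameter fingerprint); a rerun
# with unchanged inputs skips completed stages unless forced.

#' Read and validate a run configuration
#'
#' The config is a YAML file. Required blocks: `output_dir`; `grid` (`crs`,
#' `cell_size` in meters — default 1000 —, `extent` as
#' `[xmin, ymin, xmax, ymax]` meters); `inputs` (`pca` and optional `oecm`
#' file lists, `habitats` as a list of `{name, paths}` blocks, `zones`,
#' `ocean`). Optional: `tau` (default 0.3), `filter` (see
#' [filter_rules()]), `attr_map` overrides, `default_point_area_km2`
#' (default 1), `input_crs` (default `"longlat"`; use `"planar"` for
#' synthetic worlds), and a `synthetic` block (a seed plus
#' [synth_world_spec()] arguments) that generates the inputs in place of
#' real files.
#'
#' @param path YAML config file.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$config_dir <- dirname(normalizePath(path))
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A config list (as parsed from YAML).
#' @export
validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (is.null(cfg$output_dir)) stop("config: output_dir is required")
  cfg$tau <- cfg$tau %||% 0.3
  if (!is.numeric(cfg$tau) || cfg$tau <= 0 || cfg$tau >= 1) {
    stop("config: tau must be in (0, 1), got ", cfg$tau)
  }
  cfg$grid <- cfg$grid %||% list()
  cfg$grid$cell_size <- cfg$grid$cell_size %||% 1000
  if (cfg$grid$cell_size <= 0) stop("config: grid cell_size must be > 0")
  cfg$grid$crs <- cfg$grid$crs %||% "behrmann"
  cfg$default_point_area_km2 <- cfg$default_point_area_km2 %||% 1
  cfg$input_crs <- cfg$input_crs %||% "longlat"
  f <- cfg$filter %||% list()
  cfg$rules <- filter_rules(
    excluded_statuses = unlist(f$excluded_statuses) %||%
      c("Proposed", "Not Reported"),
    mab_pattern = f$mab_pattern %||% "Man and( the)? Biosphere",
    drop_points_without_area = f$drop_points_without_area %||% TRUE
  )
  if (is.null(cfg$synthetic)) {
    for (role in c("zones", "ocean")) {
      if (is.null(cfg$inputs[[role]])) {
        stop("config: inputs$", role, " is required")
      }
    }
    if (is.null(cfg$inputs$pca)) stop("config: inputs$pca is required")
    if (is.null(cfg$inputs$habitats) || length(cfg$inputs$habitats) == 0L) {
      stop("config: inputs$habitats must list at least one habitat block")
    }
    resolve <- function(p) {
      if (!is.null(cfg$config_dir) && !file.exists(p)) {
        p2 <- file.path(cfg$config_dir, p)
        if (file.exists(p2)) return(p2)
      }
      p
    }
    paths <- c(unlist(cfg$inputs$pca), unlist(cfg$inputs$oecm),
               cfg$inputs$zones, cfg$inputs$ocean,
               unlist(lapply(cfg$inputs$habitats, function(h) h$paths)))
    paths <- vapply(paths, resolve, character(1))
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0) {
      stop("config: input path(s) do not exist: ",
           paste(missing, collapse = ", "))
    }
    cfg$inputs$pca <- vapply(unlist(cfg$inputs$pca), resolve, character(1))
    cfg$inputs$oecm <- if (length(cfg$inputs$oecm))
      vapply(unlist(cfg$inputs$oecm), resolve, character(1)) else character(0)
    cfg$inputs$zones <- resolve(cfg$inputs$zones)
    cfg$inputs$ocean <- resolve(cfg$inputs$ocean)
    cfg$inputs$habitats <- lapply(cfg$inputs$habitats, function(h) {
      h$paths <- vapply(unlist(h$paths), resolve, character(1))
      h
    })
    if (is.null(cfg$grid$extent) || length(cfg$grid$extent) != 4L) {
      stop("config: grid extent [xmin, ymin, xmax, ymax] is required")
    }
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

stage_names <- c("prepare-pca", "prepare-habitats", "zones", "counts",
                 "indexes")

params_fingerprint <- function(params) {
  as.character(jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA))
}

manifest_path <- function(out_dir, stage) {
  file.path(out_dir, paste0("manifest_", gsub("-", "_", stage), ".json"))
}

stage_up_to_date <- function(out_dir, stage, inputs, params, outputs) {
  mp <- manifest_path(out_dir, stage)
  if (!file.exists(mp) || !all(file.exists(outputs))) return(FALSE)
  m <- tryCatch(jsonlite::read_json(mp), error = function(e) NULL)
  if (is.null(m)) return(FALSE)
  dig <- unname(tools::md5sum(inputs))
  identical(unlist(m$input_digests), dig) &&
    identical(m$params, params_fingerprint(params))
}

write_manifest <- function(out_dir, stage, inputs, params, outputs) {
  jsonlite::write_json(list(
    stage = stage,
    input_digests = unname(tools::md5sum(inputs)),
    inputs = inputs,
    params = params_fingerprint(params),
    outputs = outputs,
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  ), manifest_path(out_dir, stage), auto_unbox = TRUE)
}

#' Run the index pipeline
#'
#' Executes the stages in order, writing each stage's artifact (ASCII-grid
#' rasters and CSV tables) into the config's `output_dir` together with a
#' manifest of input digests. When a stage's inputs and parameters are
#' unchanged and its outputs exist, the stage is skipped unless
#' `force = TRUE`. A `synthetic` block in the config generates the input
#' files first (stage `synth`).
#'
#' @param config A [read_run_config()] result (or a config list, validated
#'   on entry).
#' @param stages Which stages to run (default: all, in order).
#' @param force Re-run stages even when up to date.
#' @param verbose Print per-stage progress.
#' @return A list: `index_table`, `ratios`, `counts`, `summary`, paths of
#'   written artifacts, and the per-stage `log` (dropped-record counts per
#'   filter reason, pixel totals per habitat, zone overlap conflicts,
#'   skipped stages).
#' @export
run_pipeline <- function(config, stages = stage_names, force = FALSE,
                         verbose = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else
    validate_run_config(config)
  stages <- match.arg(stages, stage_names, several.ok = TRUE)
  out_dir <- cfg$output_dir
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output_dir: ", out_dir)
  }
  say <- function(...) if (verbose) message(...)
  log <- list(skipped = character(0))

  # synthetic mode: materialize the world as input files first
  if (!is.null(cfg$synthetic)) {
    world_dir <- file.path(out_dir, "world")
    sargs <- cfg$synthetic
    sargs$protection <- if (!is.null(sargs$protection))
      do.call(rbind, lapply(sargs$protection, unlist)) else NULL
    spec <- do.call(synth_world_spec, sargs)
    world <- generate_world(spec)
    files <- write_world(world, world_dir)
    cfg$inputs <- list(
      pca = unname(files["pca"]),
      oecm = character(0),
      zones = unname(files["zones"]),
      ocean = unname(files["ocean"]),
      habitats = lapply(names(world$habitats), function(h) {
        list(name = h, paths = unname(files[paste0("habitat_", h)]))
      })
    )
    cfg$input_crs <- world$crs
    cfg$grid$crs <- world$crs
    cfg$grid$extent <- world$extent
    say("synth: world written to ", world_dir)
  }

  grid <- build_grid(as.numeric(unlist(cfg$grid$extent)),
                     cell_size = cfg$grid$cell_size, crs = cfg$grid$crs)
  grid_params <- cfg$grid

  pca_path <- file.path(out_dir, "pca.asc")
  hab_blocks <- cfg$inputs$habitats
  hab_names <- vapply(hab_blocks, function(h) h$name, character(1))
  hab_paths <- file.path(out_dir, paste0("habitat_", hab_names, ".asc"))
  prot_paths <- file.path(out_dir, paste0("protected_", hab_names, ".asc"))
  zone_raster_path <- file.path(out_dir, "zone_raster.asc")
  zone_lookup_path <- file.path(out_dir, "zone_lookup.csv")
  counts_path <- file.path(out_dir, "counts.csv")

  run_stage <- function(stage, inputs, params, outputs, fn) {
    if (!force && stage_up_to_date(out_dir, stage, inputs, params, outputs)) {
      say(stage, ": up to date, skipped")
      log$skipped <<- c(log$skipped, stage)
      return(invisible(NULL))
    }
    say(stage, ": running")
    res <- tryCatch(fn(), error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    write_manifest(out_dir, stage, inputs, params, outputs)
    res
  }

  pca_attr_map <- unlist(cfg$attr_map$pca) %||%
    c(id = "WDPAID", status = "STATUS", designation = "DESIG_ENG",
      rep_area = "REP_AREA")

  if ("prepare-pca" %in% stages) {
    run_stage("prepare-pca",
              inputs = c(cfg$inputs$pca, cfg$inputs$oecm),
              params = list(grid = grid_params, rules = unclass(cfg$rules),
                            attr_map = as.list(pca_attr_map)),
              outputs = pca_path, fn = function() {
      recs <- list()
      for (p in cfg$inputs$pca) {
        recs[[length(recs) + 1L]] <-
          read_pca_file(p, pca_attr_map, "protected_area", cfg$input_crs)
      }
      for (p in cfg$inputs$oecm) {
        recs[[length(recs) + 1L]] <-
          read_pca_file(p, pca_attr_map, "oecm", cfg$input_crs)
      }
      all <- do.call(rbind, recs)
      attr(all, "crs") <- attr(recs[[1]], "crs")
      class(all) <- class(recs[[1]])
      r <- prepare_pca_raster(all, cfg$rules, grid)
      log$pca <<- attr(r, "log")
      write_audit_log(filter_pca(all, cfg$rules),
                      file.path(out_dir, "pca_audit.tsv"))
      write_presence_raster(r, pca_path)
    })
  }

  if ("prepare-habitats" %in% stages) {
    for (k in seq_along(hab_blocks)) {
      hb <- hab_blocks[[k]]
      run_stage(paste0("prepare-habitats:", hb$name),
                inputs = c(hb$paths, pca_path),
                params = list(grid = grid_params,
                              default_point_area_km2 =
                                cfg$default_point_area_km2),
                outputs = c(hab_paths[k], prot_paths[k]), fn = function() {
        lay <- read_habitat_files(hb$paths, hb$name,
                                  default_crs = cfg$input_crs)
        hr <- prepare_habitat_raster(lay, grid, cfg$default_point_area_km2)
        pr <- protected_habitat_raster(hr, read_presence_raster(pca_path))
        log$habitat_pixels[[hb$name]] <<- pixel_count(hr)
        write_presence_raster(hr, hab_paths[k])
        write_presence_raster(pr, prot_paths[k])
      })
    }
  }

  if ("zones" %in% stages) {
    run_stage("zones",
              inputs = c(cfg$inputs$zones, cfg$inputs$ocean),
              params = list(grid = grid_params,
                            attr_map = cfg$attr_map$zones %||% list()),
              outputs = c(zone_raster_path, zone_lookup_path),
              fn = function() {
      zmap <- unlist(cfg$attr_map$zones) %||%
        c(zone_id = "ISO_TER1", landlocked = "LANDLOCKED",
          disputed = "DISPUTED", joint_regime = "JOINT_REGIME")
      jur <- read_zones_file(cfg$inputs$zones, zmap, cfg$input_crs)
      ocean <- read_vector_layer(cfg$inputs$ocean, cfg$input_crs)$geometry[[1]]
      zs <- build_zoneset(jur, ocean, grid, crs = attr(jur, "crs"))
      log$zones <<- zs$log
      write_asc_matrix(zs$zone_raster, grid, zone_raster_path)
      utils::write.csv(cbind(index = seq_len(nrow(zs$zones)), zs$zones),
                       zone_lookup_path, row.names = FALSE)
    })
  }

  if ("counts" %in% stages) {
    run_stage("counts",
              inputs = c(hab_paths, prot_paths, zone_raster_path,
                         zone_lookup_path),
              params = list(), outputs = counts_path, fn = function() {
      zs <- read_zoneset_artifacts(zone_raster_path, zone_lookup_path)
      hr <- stats::setNames(lapply(hab_paths, read_presence_raster), hab_names)
      pr <- stats::setNames(lapply(prot_paths, read_presence_raster), hab_names)
      counts <- zonal_counts(hr, pr, zs)
      log$unassigned <<- attr(counts, "log")$unassigned_habitat_pixels
      utils::write.csv(counts, counts_path, row.names = FALSE)
    })
  }

  result <- NULL
  if ("indexes" %in% stages) {
    index_files <- file.path(out_dir,
                             c("zone_indexes.csv", "zone_habitat_indexes.csv",
                               "zone_habitat_targeted.csv",
                               "global_summary.csv"))
    run_stage("indexes",
              inputs = c(counts_path, hab_paths, prot_paths,
                         zone_raster_path, zone_lookup_path),
              params = list(tau = cfg$tau), outputs = index_files,
              fn = function() {
      counts <- utils::read.csv(counts_path, stringsAsFactors = FALSE)
      ratios <- per_habitat_ratios(counts)
      it <- aggregate_indexes(ratios, tau = cfg$tau)
      zs <- read_zoneset_artifacts(zone_raster_path, zone_lookup_path)
      hr <- stats::setNames(lapply(hab_paths, read_presence_raster), hab_names)
      pr <- stats::setNames(lapply(prot_paths, read_presence_raster), hab_names)
      gs <- global_summary(hr, pr, zs)
      write_index_tables(it, ratios = NULL, gs, out_dir,
                         metadata = list(
                           grid_crs = grid$crs, cell_size_m = grid$cell_size,
                           n_rows = grid$n_rows, n_cols = grid$n_cols,
                           input_digests = paste(
                             unname(tools::md5sum(counts_path)),
                             collapse = " ")))
    })
    counts <- utils::read.csv(counts_path, stringsAsFactors = FALSE)
    ratios <- per_habitat_ratios(counts)
    it <- aggregate_indexes(ratios, tau = cfg$tau)
    result <- list(index_table = it, ratios = ratios, counts = counts,
                   summary = read_index_table(
                     file.path(out_dir, "global_summary.csv")))
  }
  c(result, list(
    grid = grid, output_dir = out_dir, log = log,
    artifacts = list(pca = pca_path, habitats = hab_paths,
                     protected = prot_paths, zone_raster = zone_raster_path,
                     zone_lookup = zone_lookup_path, counts = counts_path)
  ))
}

# Rebuild a zone_set from its persisted artifacts (integer raster + lookup).
read_zoneset_artifacts <- function(zone_raster_path, zone_lookup_path) {
  r <- read_asc_matrix(zone_raster_path)
  lk <- utils::read.csv(zone_lookup_path, stringsAsFactors = FALSE)
  zr <- r$cells
  storage.mode(zr) <- "integer"
  structure(list(zones = lk[order(lk$index),
                            c("zone_id", "kind"), drop = FALSE],
                 zone_raster = zr, grid = r$grid,
                 log = list()), class = "zone_set")
}
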