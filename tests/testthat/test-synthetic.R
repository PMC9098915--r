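run_raster_pipeline <- function(world, cell_size = 1000) {
  grid <- build_grid(world$extent, cell_size, crs = "planar")
  pca <- suppressWarnings(prepare_pca_raster(world$pca, filter_rules(), grid))
  hr <- lapply(world$habitats, prepare_habitat_raster, grid = grid)
  pr <- lapply(hr, protected_habitat_raster, pca = pca)
  zs <- build_zoneset(world$jurisdictions, world$ocean, grid, crs = "planar")
  counts <- zonal_counts(hr, pr, zs)
  per_habitat_ratios(counts)
}

test_that("the same seed reproduces the world file-for-file", {
  spec <- small_world_spec(seed = 5)
  d1 <- file.path(tempdir(), "w1"); d2 <- file.path(tempdir(), "w2")
  f1 <- write_world(generate_world(spec), d1)
  f2 <- write_world(generate_world(spec), d2)
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # a different seed gives a different world
  f3 <- write_world(generate_world(small_world_spec(seed = 6)),
                    file.path(tempdir(), "w3"))
  expect_false(identical(unname(tools::md5sum(f1["pca"])),
                         unname(tools::md5sum(f3["pca"]))))
})

test_that("ground truth matches the exact vector-geometry oracle", {
  w <- generate_world(small_world_spec(seed = 2))
  or <- exact_oracle(w)
  m <- merge(w$ground_truth, or, by = c("zone_id", "habitat"),
             suffixes = c(".gt", ".or"))
  expect_equal(m$extent_km2.gt, m$extent_km2.or, tolerance = 1e-9)
  expect_equal(m$protected_km2.gt, m$protected_km2.or, tolerance = 1e-9)
  # constructed protection fractions are exact
  pres <- w$ground_truth[w$ground_truth$extent_km2 > 0, ]
  expect_equal(pres$protected_km2 / pres$extent_km2, pres$p_target,
               tolerance = 1e-9)
})

test_that("the oracle clips straddling habitats across zones exactly", {
  # a 10 x 10 km square habitat straddling two zones 70/30 by construction
  jur <- data.frame(zone_id = c("L", "R"), stringsAsFactors = FALSE)
  jur$geometry <- list(hp_rect(0, 0, 7000, 20000), hp_rect(7000, 0, 20000, 20000))
  hab <- habitat_layer("h", list(hp_rect(0, 5000, 10000, 15000)), crs = "planar")
  pca <- pca_records("p", list(hp_rect(0, 5000, 5000, 15000)), "Designated",
                     crs = "planar")
  world <- list(jurisdictions = jur, habitats = list(h = hab), pca = pca)
  or <- exact_oracle(world)
  expect_equal(or$extent_km2[or$zone_id == "L"], 70)
  expect_equal(or$extent_km2[or$zone_id == "R"], 30)
  # protection covers the left 5 km slab: 50 km^2, all inside L
  expect_equal(or$protected_km2[or$zone_id == "L"], 50)
  expect_equal(or$protected_km2[or$zone_id == "R"], 0)
})

test_that("full protection and pure-decoy worlds hit the index extremes", {
  n_zones <- 4L; n_h <- 2L
  all_one <- matrix(1, n_zones, n_h)
  w1 <- generate_world(small_world_spec(seed = 3, protection = all_one))
  r1 <- run_raster_pipeline(w1)
  expect_true(all(abs(r1$lphpi[r1$E > 0] - 1) < 1e-12))
  # p = 0 everywhere: only decoys remain and the filters must drop them all
  all_zero <- matrix(0, n_zones, n_h)
  w0 <- generate_world(small_world_spec(seed = 3, protection = all_zero))
  expect_gt(nrow(w0$pca), 0)  # decoys are present
  r0 <- suppressWarnings(run_raster_pipeline(w0))
  expect_true(all(r0$lphpi[r0$E > 0] == 0))
})

test_that("decoy records change no index value", {
  spec_d <- small_world_spec(seed = 4, decoys = TRUE)
  spec_n <- small_world_spec(seed = 4, decoys = FALSE)
  rd <- run_raster_pipeline(generate_world(spec_d))
  rn <- run_raster_pipeline(generate_world(spec_n))
  expect_equal(rd$lphpi, rn$lphpi)
  expect_equal(rd$gphpi, rn$gphpi)
})

test_that("the pipeline recovers ground-truth protection within +/-0.02 at 1 km", {
  w <- generate_world(synth_world_spec(seed = 11))
  ratios <- run_raster_pipeline(w)
  m <- merge(ratios, w$ground_truth, by = c("zone_id", "habitat"))
  gt_lphpi <- ifelse(m$extent_km2 > 0, m$protected_km2 / m$extent_km2, NA)
  err_1km <- abs(m$lphpi - gt_lphpi)
  expect_lt(max(err_1km, na.rm = TRUE), 0.02)
  # halving the cell size tightens recovery to +/-0.005
  ratios500 <- run_raster_pipeline(w, cell_size = 500)
  m5 <- merge(ratios500, w$ground_truth, by = c("zone_id", "habitat"))
  gt5 <- ifelse(m5$extent_km2 > 0, m5$protected_km2 / m5$extent_km2, NA)
  expect_lt(max(abs(m5$lphpi - gt5), na.rm = TRUE), 0.005)
})

test_that("infeasible specs are rejected with a diagnostic", {
  spec <- synth_world_spec(seed = 1, world_km = c(40, 40),
                           n_jurisdictions = 2L, n_habitats = 2L,
                           n_patches = 30L, patch_area_km2 = c(50, 100))
  expect_error(generate_world(spec), "infeasible")
})

test_that("world files load back through the standard readers", {
  w <- generate_world(small_world_spec(seed = 8))
  d <- file.path(tempdir(), "wload")
  files <- write_world(w, d)
  pca <- read_pca_file(files["pca"], source = "protected_area")
  expect_equal(nrow(pca), nrow(w$pca))
  expect_equal(attr(pca, "crs"), "planar")
  zones <- read_zones_file(files["zones"])
  expect_equal(zones$zone_id, w$jurisdictions$zone_id)
  hab_file <- files[paste0("habitat_", names(w$habitats)[1])]
  lay <- read_habitat_files(hab_file, names(w$habitats)[1])
  expect_equal(length(lay$geometry), length(w$habitats[[1]]$geometry))
  # unsupported formats fail loudly
  expect_error(read_vector_layer("foo.gpkg"), "does not exist")
  gpkg <- file.path(tempdir(), "x.gpkg"); file.create(gpkg)
  expect_error(read_vector_layer(gpkg), "GeoJSON")
})
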