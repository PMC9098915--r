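two_zone_world <- function() {
  jur <- data.frame(zone_id = c("AAA", "BBB"), stringsAsFactors = FALSE)
  jur$geometry <- list(hp_rect(0, 0, 10000, 10000),
                       hp_rect(10000, 0, 20000, 10000))
  list(jur = jur, ocean = hp_rect(0, 0, 20000, 20000),
       grid = build_grid(c(0, 0, 20000, 20000), 1000))
}

test_that("zones partition the ocean with ABNJ as the remainder", {
  w <- two_zone_world()
  zs <- build_zoneset(w$jur, w$ocean, w$grid, crs = "planar")
  expect_equal(zs$zones$zone_id, c("AAA", "BBB", "ABNJ"))
  expect_equal(zs$zones$kind, c("jurisdiction", "jurisdiction", "abnj"))
  counts <- tabulate(zs$zone_raster, 3)
  expect_equal(counts, c(100L, 100L, 200L))
  expect_equal(sum(zs$zone_raster != 0L), 400L)  # the whole ocean
})

test_that("flagged jurisdictions are removed before rasterization", {
  w <- two_zone_world()
  w$jur$landlocked <- c(FALSE, TRUE)
  zs <- build_zoneset(w$jur, w$ocean, w$grid, crs = "planar")
  expect_false("BBB" %in% zs$zones$zone_id)
  expect_equal(zs$log$dropped_zones, "BBB")
  # BBB's cells become ABNJ (they are ocean, assigned to no jurisdiction)
  expect_equal(tabulate(zs$zone_raster, 2), c(100L, 300L))
  for (flag in c("disputed", "joint_regime")) {
    w2 <- two_zone_world()
    w2$jur[[flag]] <- c(TRUE, FALSE)
    expect_false("AAA" %in%
                   build_zoneset(w2$jur, w2$ocean, w2$grid,
                                 crs = "planar")$zones$zone_id)
  }
})

test_that("overlapping zones resolve deterministically by zone_id order", {
  jur <- data.frame(zone_id = c("BBB", "AAA"), stringsAsFactors = FALSE)
  # 3-cell overlap along a row
  jur$geometry <- list(hp_rect(2000, 0, 8000, 1000),
                       hp_rect(0, 0, 5000, 1000))
  grid <- build_grid(c(0, 0, 10000, 10000), 1000)
  zs <- build_zoneset(jur, hp_rect(0, 0, 10000, 10000), grid, crs = "planar")
  expect_equal(zs$log$overlap_cells, 3L)
  # AAA sorts first: it owns the 3 shared cells
  idx_a <- which(zs$zones$zone_id == "AAA")
  idx_b <- which(zs$zones$zone_id == "BBB")
  expect_equal(tabulate(zs$zone_raster, 3)[c(idx_a, idx_b)], c(5L, 3L))
  expect_equal(sum(tabulate(zs$zone_raster, 2)[c(idx_a, idx_b)]), 8L)
})

test_that("duplicate zone ids and empty oceans are handled explicitly", {
  w <- two_zone_world()
  w$jur$zone_id <- c("AAA", "AAA")
  expect_error(build_zoneset(w$jur, w$ocean, w$grid, crs = "planar"),
               "duplicate")
  w2 <- two_zone_world()
  expect_warning(zs <- build_zoneset(w2$jur, NULL, w2$grid, crs = "planar"),
                 "ABNJ")
  expect_false("ABNJ" %in% zs$zones$zone_id)
})

test_that("zonal counts split habitat and protected pixels per zone", {
  w <- two_zone_world()
  zs <- build_zoneset(w$jur, w$ocean, w$grid, crs = "planar")
  # 20-pixel habitat inside AAA, half protected
  hab <- raster_from_cells(w$grid, rep(15:18, each = 5), rep(1:5, times = 4))
  prot <- raster_from_cells(w$grid, rep(15:16, each = 5), rep(1:5, times = 2))
  counts <- zonal_counts(list(h = hab), list(h = prot), zs)
  row_a <- counts[counts$zone_id == "AAA", ]
  expect_equal(c(row_a$E, row_a$P), c(20L, 10L))
  expect_true(row_a$present)
  # absent rows are retained with E = 0 and flagged
  row_b <- counts[counts$zone_id == "BBB", ]
  expect_equal(row_b$E, 0L)
  expect_false(row_b$present)
  expect_equal(unname(attr(counts, "E_glob")["h"]), 20L)
})

test_that("habitat only in ABNJ lands in the ABNJ row", {
  w <- two_zone_world()
  zs <- build_zoneset(w$jur, w$ocean, w$grid, crs = "planar")
  hab <- raster_from_cells(w$grid, rep(3, 7), 4:10)  # top half = ABNJ
  counts <- zonal_counts(list(h = hab), list(h = presence_raster(w$grid)), zs)
  expect_equal(counts$E[counts$zone_id == "ABNJ"], 7L)
  expect_equal(sum(counts$E[counts$zone_id != "ABNJ"]), 0L)
})

test_that("partition identity: zone sums equal assigned habitat pixels", {
  w <- two_zone_world()
  zs <- build_zoneset(w$jur, w$ocean, w$grid, crs = "planar")
  set.seed(9)
  m <- matrix(rbinom(400, 1, 0.4), 20, 20)
  hab <- presence_raster(w$grid, m)
  counts <- zonal_counts(list(h = hab), list(h = presence_raster(w$grid)), zs)
  assigned <- sum(hab$cells == 1L & zs$zone_raster != 0L)
  expect_equal(sum(counts$E), assigned)
  expect_equal(unname(attr(counts, "E_glob")["h"]), assigned)
})

test_that("count tables are invariant to habitat order and validate inputs", {
  w <- two_zone_world()
  zs <- build_zoneset(w$jur, w$ocean, w$grid, crs = "planar")
  h1 <- raster_from_cells(w$grid, 15, 2)
  h2 <- raster_from_cells(w$grid, 12, 14)
  z <- presence_raster(w$grid)
  c12 <- zonal_counts(list(a = h1, b = h2), list(a = z, b = z), zs)
  c21 <- zonal_counts(list(b = h2, a = h1), list(b = z, a = z), zs)
  key <- function(d) d[order(d$zone_id, d$habitat), c("zone_id", "habitat", "E", "P")]
  expect_equal(key(as.data.frame(c12)), key(as.data.frame(c21)),
               ignore_attr = TRUE)
  expect_error(zonal_counts(list(a = h1), list(b = z), zs), "protected companion")
  expect_error(zonal_counts(list(a = h1), list(a = h2), zs),
               "exceeds habitat")
})
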