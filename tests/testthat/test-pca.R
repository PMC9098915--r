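make_records <- function() {
  sq <- function(x0) hp_rect(x0, 0, x0 + 3000, 3000)
  pca_records(
    id = sprintf("r%02d", 1:10),
    geometry = c(lapply(seq(0, 8 * 4000, by = 4000), sq),
                 list(hp_point(1500, 9000))),
    status = c("Designated", "Designated",            # MAB pair
               "Proposed", "Proposed", NA,            # bad statuses (NA -> Not Reported)
               "Designated", "Inscribed", "Adopted", "Established",
               "Designated"),                         # point without area
    designation = c("UNESCO Man and the Biosphere Reserve",
                    "Man and Biosphere Reserve",
                    rep("Marine Reserve", 8)),
    reported_area_km2 = c(rep(NA, 9), NA),
    crs = "planar"
  )
}

test_that("filter drops MAB, excluded statuses, and area-less points with one reason each", {
  f <- filter_pca(make_records(), filter_rules())
  expect_equal(nrow(f$kept), 4L)
  expect_setequal(f$kept$id, c("r06", "r07", "r08", "r09"))
  counts <- table(f$dropped$reason)
  expect_equal(as.integer(counts[c("mab", "status", "point_without_area")]),
               c(2L, 3L, 1L))
  # precedence: a Proposed MAB record is dropped as MAB, not as status
  rec <- pca_records("x", list(hp_rect(0, 0, 1, 1)), "Proposed",
                     "Man and the Biosphere core area", crs = "planar")
  expect_equal(filter_pca(rec)$dropped$reason, "mab")
})

test_that("kept and dropped partition the input and filtering is idempotent", {
  recs <- make_records()
  f <- filter_pca(recs)
  expect_setequal(c(f$kept$id, f$dropped$id), recs$id)
  f2 <- filter_pca(f$kept)
  expect_equal(nrow(f2$dropped), 0L)
  expect_equal(f2$kept$id, f$kept$id)
  # empty input is fine
  empty <- filter_pca(recs[0, ])
  expect_equal(nrow(empty$kept), 0L)
  expect_equal(nrow(empty$dropped), 0L)
})

test_that("status matching is exact and configurable; missing status is Not Reported", {
  recs <- pca_records(c("a", "b", "c"),
                      list(hp_rect(0, 0, 1, 1), hp_rect(2, 0, 3, 1),
                           hp_rect(4, 0, 5, 1)),
                      status = c("proposed", "Designated", NA),
                      crs = "planar")
  f <- filter_pca(recs)  # lowercase "proposed" is not excluded
  expect_setequal(f$kept$id, c("a", "b"))
  expect_equal(f$dropped$reason, "status")
  custom <- filter_rules(excluded_statuses = c("proposed", "Not Reported"))
  expect_setequal(filter_pca(recs, custom)$kept$id, "b")
})

test_that("prepare_pca_raster composes filter, buffer, rasterize and merge", {
  g <- build_grid(c(0, 0, 20000, 20000), 1000)
  # all records Proposed -> empty raster with a warning
  bad <- pca_records("p1", list(hp_rect(0, 0, 9000, 9000)), "Proposed",
                     crs = "planar")
  expect_warning(r0 <- prepare_pca_raster(bad, filter_rules(), g), "empty")
  expect_equal(pixel_count(r0), 0)
  # a polygon covering 12 cell centers -> 12 pixels (4 cols x 3 rows)
  rec <- pca_records("p2", list(hp_rect(100, 200, 4100, 3200)), "Designated",
                     crs = "planar")
  expect_equal(pixel_count(prepare_pca_raster(rec, grid = g)), 12)
  # overlapping designated polygons union, never sum
  two <- pca_records(c("a", "b"),
                     list(hp_rect(0, 0, 5000, 3000), hp_rect(3000, 0, 8000, 3000)),
                     "Designated", crs = "planar")
  r2 <- prepare_pca_raster(two, grid = g)
  expect_equal(pixel_count(r2), 8 * 3)
  # record order does not matter
  two_rev <- two[2:1, ]
  attr(two_rev, "crs") <- "planar"
  class(two_rev) <- class(two)
  expect_equal(prepare_pca_raster(two_rev, grid = g)$cells, r2$cells)
})

test_that("points with reported area become circles matching that area", {
  g <- build_grid(c(0, 0, 20000, 20000), 1000)
  # 1 km^2 circle centered on a cell center covers exactly that cell
  rec <- pca_records("pt", list(hp_point(10500, 10500)), "Designated",
                     reported_area_km2 = 1, crs = "planar")
  r <- prepare_pca_raster(rec, grid = g)
  expect_equal(pixel_count(r), 1)
  expect_equal(r$cells[10, 11], 1L)
  # larger circle: pixel count approximates the area
  rec2 <- pca_records("pt2", list(hp_point(10500, 10500)), "Designated",
                      reported_area_km2 = 80, crs = "planar")
  expect_lt(abs(pixel_count(prepare_pca_raster(rec2, grid = g)) - 80), 12)
})

test_that("the processing log and audit file account for every record", {
  recs <- make_records()
  g <- build_grid(c(0, 0, 40000, 12000), 1000)
  r <- prepare_pca_raster(recs, grid = g)
  log <- attr(r, "log")
  expect_equal(log$n_input, 10L)
  expect_equal(log$n_kept, 4L)
  expect_equal(unname(log$dropped_by_reason), c(2L, 3L, 1L))
  path <- file.path(tempdir(), "audit.tsv")
  write_audit_log(filter_pca(recs), path)
  audit <- read.delim(path)
  expect_equal(nrow(audit), 10L)
  expect_equal(sum(audit$action == "kept"), 4L)
})

test_that("structurally invalid geometries are rejected and logged by id", {
  g <- build_grid(c(0, 0, 10000, 10000), 1000)
  degenerate <- hp_polygon(cbind(c(0, 1000, 2000), c(0, 0, 0)))
  recs <- pca_records(c("good", "flat"),
                      list(hp_rect(0, 0, 3000, 3000), degenerate),
                      "Designated", crs = "planar")
  r <- prepare_pca_raster(recs, grid = g)
  expect_equal(attr(r, "log")$invalid_geometry_ids, "flat")
  expect_equal(pixel_count(r), 9)
})
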