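counts_df <- function(zone, hab, E, P) {
  data.frame(zone_id = zone, habitat = hab, E = E, P = P,
             stringsAsFactors = FALSE)
}

test_that("per-habitat ratios follow their definitions exactly", {
  counts <- counts_df(c("J1", "J2", "J2"), c("h1", "h1", "h2"),
                      E = c(50, 0, 40), P = c(50, 0, 10))
  attr(counts, "E_glob") <- c(h1 = 50, h2 = 400)
  r <- per_habitat_ratios(counts)
  j1 <- r[r$zone_id == "J1" & r$habitat == "h1", ]
  expect_equal(c(j1$lphpi, j1$gphpi), c(1, 1))
  j2h2 <- r[r$zone_id == "J2" & r$habitat == "h2", ]
  expect_equal(c(j2h2$lphpi, j2h2$gphpi), c(0.25, 0.025))
  # absent habitat: NA ratios, not zero
  j2h1 <- r[r$zone_id == "J2" & r$habitat == "h1", ]
  expect_true(is.na(j2h1$lphpi) && is.na(j2h1$gphpi))
  # zero protection is a true zero
  r0 <- per_habitat_ratios(counts_df("J", "h", 200, 0))
  expect_equal(r0$lphpi, 0)
})

test_that("ratio preconditions and degenerate habitats are handled", {
  expect_error(per_habitat_ratios(counts_df("J", "h", 5, 7)), "P <= E")
  ct <- counts_df(c("J", "J"), c("h", "void"), c(10, 0), c(5, 0))
  expect_warning(r <- per_habitat_ratios(ct), "zero global extent")
  expect_false("void" %in% r$habitat)
})

test_that("zone averages cover present habitats only", {
  ct <- counts_df(rep("J", 4), paste0("h", 1:4),
                  E = c(100, 100, 0, 0), P = c(20, 40, 0, 0))
  it <- aggregate_indexes(suppressWarnings(per_habitat_ratios(ct)), tau = 0.3)
  expect_equal(it$LPHPI, 0.3)        # mean(0.2, 0.4)
  expect_equal(it$n_habitats, 2L)
  # one habitat present at 0.8, three absent -> 0.8, not 0.2
  ct2 <- counts_df(rep("J", 4), paste0("h", 1:4),
                   E = c(100, 0, 0, 0), P = c(80, 0, 0, 0))
  expect_equal(
    aggregate_indexes(suppressWarnings(per_habitat_ratios(ct2)))$LPHPI, 0.8)
  # zones with no habitat present vanish from the table
  ct3 <- counts_df(c("J1", "J2"), "h1", E = c(100, 0), P = c(10, 0))
  it3 <- aggregate_indexes(per_habitat_ratios(ct3))
  expect_equal(it3$zone_id, "J1")
})

test_that("the targeted score breaks even exactly at the target fraction", {
  ct <- counts_df("J", "h", E = 100, P = 30)
  it <- aggregate_indexes(per_habitat_ratios(ct), tau = 0.3)
  expect_equal(it$targeted, 0)
  ph <- attr(it, "per_habitat")
  expect_equal(ph$targeted, 0)
  # tau is configurable; lowering it raises the score by (0.3-tau)*E/E_glob
  it1 <- aggregate_indexes(per_habitat_ratios(ct), tau = 0.1)
  expect_equal(it1$targeted, 0.2 * 100 / 100)
  expect_error(aggregate_indexes(per_habitat_ratios(ct), tau = 0), "tau")
})

test_that("index identities hold on randomized count tables", {
  set.seed(77)
  tau <- 0.3
  for (case in 1:200) {
    ct <- random_count_table()
    r <- suppressWarnings(per_habitat_ratios(ct))
    it <- aggregate_indexes(r, tau = tau)
    ph <- attr(it, "per_habitat")
    pres <- ph[ph$E > 0, ]
    # identity A: gphpi = lphpi * E / E_glob
    expect_equal(pres$gphpi, pres$lphpi * pres$E / pres$E_glob)
    # identity B: zone sum of gphpi is the habitat's global protected share
    for (h in unique(pres$habitat)) {
      hh <- pres[pres$habitat == h, ]
      expect_equal(sum(hh$gphpi), sum(hh$P) / hh$E_glob[1])
    }
    # sign law: targeted > 0 iff lphpi > tau
    expect_equal(pres$targeted > 0, pres$lphpi > tau)
    # ranges
    expect_true(all(pres$lphpi >= 0 & pres$lphpi <= 1))
    expect_true(all(pres$gphpi >= 0 & pres$gphpi <= 1))
    expect_true(all(it$LPHPI >= 0 & it$LPHPI <= 1))
    expect_true(all(it$GPHPI >= 0 & it$GPHPI <= 1))
    expect_true(all(pres$targeted >= -tau * pres$E / pres$E_glob - 1e-12))
    expect_true(all(pres$targeted <= (1 - tau) * pres$E / pres$E_glob + 1e-12))
  }
})

test_that("adding protection never decreases any index", {
  set.seed(123)
  ct <- random_count_table()
  r1 <- suppressWarnings(per_habitat_ratios(ct))
  it1 <- aggregate_indexes(r1)
  ct2 <- ct
  room <- which(ct2$P < ct2$E)
  bump <- sample(room, max(1, length(room) %/% 2))
  ct2$P[bump] <- ct2$P[bump] + 1L
  r2 <- suppressWarnings(per_habitat_ratios(ct2))
  it2 <- aggregate_indexes(r2)
  m <- merge(as.data.frame(it1), as.data.frame(it2), by = "zone_id")
  expect_true(all(m$LPHPI.y >= m$LPHPI.x - 1e-12))
  expect_true(all(m$GPHPI.y >= m$GPHPI.x - 1e-12))
  expect_true(all(m$targeted.y >= m$targeted.x - 1e-12))
})

test_that("extent-weighted averaging is available and differs when it should", {
  ct <- counts_df(rep("J", 2), c("h1", "h2"), E = c(100, 900), P = c(100, 0))
  r <- per_habitat_ratios(ct)
  plain <- aggregate_indexes(r)
  weighted <- aggregate_indexes(r, weighted = TRUE)
  expect_equal(plain$LPHPI, 0.5)
  expect_equal(weighted$LPHPI, 0.1)
})

test_that("the global summary splits totals between jurisdictions and ABNJ", {
  jur <- data.frame(zone_id = "JJ", stringsAsFactors = FALSE)
  jur$geometry <- list(hp_rect(0, 0, 10000, 10000))
  grid <- build_grid(c(0, 0, 10000, 20000), 1000)
  zs <- build_zoneset(jur, hp_rect(0, 0, 10000, 20000), grid, crs = "planar")
  # 60 pixels in the jurisdiction, 40 in ABNJ; 30 protected, all in ABNJ
  hab <- raster_from_cells(grid, c(rep(11:16, each = 10), rep(1:4, each = 10)),
                           rep(1:10, times = 10))
  prot <- raster_from_cells(grid, rep(1:3, each = 10), rep(1:10, times = 3))
  gs <- global_summary(list(h = hab), list(h = prot), zs)
  expect_equal(gs$total_px, 100)
  expect_equal(gs$protected_px, 30)
  expect_equal(gs$prop_protected, 0.3)
  expect_equal(c(gs$jurisdiction_px, gs$abnj_px), c(60, 40))
  expect_equal(gs$prop_extent_abnj, 0.4)
  expect_equal(gs$jurisdiction_px + gs$abnj_px, gs$total_px)
  expect_equal(gs$jurisdiction_protected_px + gs$abnj_protected_px,
               gs$protected_px)
})

test_that("index tables round-trip through CSV with stable column order", {
  ct <- counts_df(c("J1", "J1", "J2"), c("h1", "h2", "h1"),
                  E = c(100, 50, 200), P = c(30, 50, 20))
  it <- aggregate_indexes(per_habitat_ratios(ct))
  dir1 <- file.path(tempdir(), "idx1")
  files <- write_index_tables(it, path = dir1,
                              metadata = list(note = "unit"))
  zi <- read_index_table(file.path(dir1, "zone_indexes.csv"))
  expect_equal(names(zi), c("zone_id", "n_habitats", "LPHPI", "GPHPI",
                            "targeted"))
  expect_equal(zi$LPHPI, it$LPHPI)
  expect_equal(zi$targeted, it$targeted, tolerance = 1e-12)
  # permuting the input rows leaves the written files identical
  ct_perm <- ct[c(3, 1, 2), ]
  it2 <- aggregate_indexes(per_habitat_ratios(ct_perm))
  dir2 <- file.path(tempdir(), "idx2")
  write_index_tables(it2, path = dir2, metadata = list(note = "unit"))
  expect_identical(readLines(file.path(dir1, "zone_indexes.csv")),
                   readLines(file.path(dir2, "zone_indexes.csv")))
  # an empty table writes a header-only file
  empty <- aggregate_indexes(per_habitat_ratios(counts_df("J", "h", 0, 0)[0, ]))
  dir3 <- file.path(tempdir(), "idx3")
  write_index_tables(empty, path = dir3)
  expect_equal(nrow(read_index_table(file.path(dir3, "zone_indexes.csv"))), 0L)
})
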