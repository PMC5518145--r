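# urban/rural sub-domain enforcement and spatial coverage

rururb_cfg <- function(hh_stratum, hh_urban, hh_rural = hh_urban) {
  sample_config(cfg_hh_per_stratum = hh_stratum, cfg_hh_per_urban = hh_urban,
                cfg_hh_per_rural = hh_rural, cfg_pop_per_psu = 10,
                cfg_sample_rururb = TRUE)
}

test_that("sub-domain swaps reach the household minimum and keep n_k", {
  # 4x4, urban column on the east edge
  urb <- matrix(0, 4, 4); urb[, 4] <- 1
  fr <- frame_from(matrix(1, 4, 4), urbanmat = urb)
  cfg <- rururb_cfg(4, 2, 2)
  rng <- gridpsu:::seeded_rng(1)

  all_rural <- fr$cell_id[match(c(0, 1, 2, 5), fr$serpentine_index)]
  s0 <- seed_set_from(fr, all_rural)
  s1 <- enforce_subdomain_minimum(s0, fr, cfg, rng)
  expect_equal(nrow(s1$seeds), 4L)                 # totals unchanged
  expect_equal(sum(s1$seeds$urban), 2L)            # exactly 2 urban after
  expect_equal(as.vector(table(s1$seeds$stratum_id)), 4L)
  expect_equal(nrow(attr(s1, "swap_log")), 2L)

  # idempotent once both minima hold
  s2 <- enforce_subdomain_minimum(s1, fr, cfg, rng)
  expect_identical(s2$seeds, s1$seeds)

  # no-op when satisfied from the start
  sat <- seed_set_from(fr, fr$cell_id[match(c(0, 3, 6, 11), fr$serpentine_index)])
  expect_equal(sum(sat$seeds$urban), 2L)
  expect_identical(enforce_subdomain_minimum(sat, fr, cfg, rng)$seeds, sat$seeds)
})

test_that("sub-domain enforcement is infeasible without urban cells", {
  fr <- frame_from(matrix(1, 3, 3), urbanmat = matrix(0, 3, 3))
  s0 <- seed_set_from(fr, fr$cell_id[1:2])
  expect_error(enforce_subdomain_minimum(s0, fr, rururb_cfg(4, 2),
                                         gridpsu:::seeded_rng(1)),
               "no urban cells")
})

test_that("swaps cross strata but drop within the candidate's stratum", {
  # stratum 1 (north) all rural; all urban cells sit in stratum 2 (south)
  urb <- matrix(0, 4, 4); urb[3:4, 1] <- 1
  st <- matrix(rep(c(1, 1, 2, 2), 4), 4, 4)
  fr <- frame_from(matrix(1, 4, 4), st, urb)
  s0 <- seed_set_from(fr, fr$cell_id[match(c(0, 1, 10, 11), fr$serpentine_index)])
  expect_equal(sum(s0$seeds$urban), 0L)
  s1 <- enforce_subdomain_minimum(s0, fr, rururb_cfg(4, 2),
                                  gridpsu:::seeded_rng(2))
  expect_equal(sum(s1$seeds$urban), 2L)
  expect_true(all(s1$seeds$stratum_id[s1$seeds$urban] == 2L))
  expect_equal(as.vector(table(s1$seeds$stratum_id)), c(2L, 2L))
})

test_that("coarse grid construction converts scale to cells per side", {
  fr100 <- frame_from(matrix(1, 4, 4), cell = 100)
  expect_equal(build_coarse_grid(fr100, 20)$cells_per_side, 200L)
  expect_equal(build_coarse_grid(fr100, 0.01)$cells_per_side, 1L)  # floor at 1
  fr1k <- frame_from(matrix(1, 4, 4), cell = 1000)
  expect_equal(build_coarse_grid(fr1k, 3)$cells_per_side, 3L)

  # a degree grid uses the centroid cell's ground size
  g <- pop_grid(matrix(1, 10, 10), origin_x = 30, origin_y = 0,
                cell_width = 0.0009, crs_label = "EPSG:4326 degrees")
  cfg <- sample_config(cfg_hh_per_stratum = 1, cfg_hh_per_urban = 1,
                       cfg_pop_per_psu = 1)
  frd <- build_frame(g, zone_grid(matrix(1, 10, 10), origin_x = 30,
                                  origin_y = 0, cell_width = 0.0009,
                                  crs_label = "EPSG:4326 degrees"), NULL, cfg)
  side <- sqrt(prod(unlist(centroid_cell_size(g)[c("side_x_m", "side_y_m")])))
  expect_equal(build_coarse_grid(frd, 2)$cells_per_side,
               as.integer(round(2000 / side)))
})

test_that("spatial coverage seeds every populated coarse cell", {
  fr <- frame_from(matrix(1, 8, 8), cell = 1000)      # 4 coarse cells at 4 km
  coarse <- build_coarse_grid(fr, 4)
  expect_equal(coarse$cells_per_side, 4L)
  expect_equal(length(unique(coarse$coarse_id)), 4L)
  # all 4 seeds initially inside the north-west coarse cell
  nw <- fr$cell_id[fr$row < 4 & fr$col < 4][1:4]
  s0 <- seed_set_from(fr, nw)
  s1 <- enforce_spatial_coverage(s0, fr, coarse, gridpsu:::seeded_rng(3))
  occ <- coarse$coarse_id[match(s1$seeds$cell_id, fr$cell_id)]
  expect_equal(sort(unique(occ)), sort(unique(coarse$coarse_id)))
  expect_equal(as.vector(table(occ)), rep(1L, 4))     # one seed each
  expect_equal(nrow(s1$seeds), 4L)

  # no-op when every coarse cell already holds a seed
  expect_identical(enforce_spatial_coverage(s1, fr, coarse,
                                            gridpsu:::seeded_rng(4))$seeds,
                   s1$seeds)
})

test_that("spatial coverage skips (with warning) when no drop is valid", {
  # 2x8 strip, west half stratum 1, east half stratum 2; one seed each.
  # Each seed is its coarse cell's only seed, so the two empty coarse cells
  # cannot be filled without moving the hole: both are skipped and logged.
  st <- matrix(2, 2, 8); st[, 1:4] <- 1
  fr <- frame_from(matrix(1, 2, 8), st, cell = 1000)
  coarse <- build_coarse_grid(fr, 2)                  # 2 km -> 2 cells/side
  expect_equal(length(unique(coarse$coarse_id)), 4L)
  s0 <- seed_set_from(fr, c(fr$cell_id[fr$col == 0][1],
                            fr$cell_id[fr$col == 4][1]))
  w <- testthat::capture_warnings(
    s1 <- enforce_spatial_coverage(s0, fr, coarse, gridpsu:::seeded_rng(5)))
  expect_equal(length(w), 2L)
  expect_true(all(grepl("left unseeded", w)))
  expect_identical(sort(s1$seeds$cell_id), sort(s0$seeds$cell_id))
  expect_true(all(attr(s1, "swap_log")$reason == "spatial_skipped"))
})
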