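# attribute assembly and vector output

make_run <- function(seed = 1, urban_rule = 0.3) {
  spec <- fixture_spec(10, 10, "blobs", strata_layout = c(1, 2),
                       urban_rule = urban_rule, seed = seed)
  pop <- make_population(spec)
  fr <- build_frame(pop, make_strata(spec), make_urban(spec, pop),
                    sample_config(cfg_hh_per_stratum = 2, cfg_hh_per_urban = 1,
                                  cfg_pop_per_psu = 30))
  cfg <- sample_config(cfg_hh_per_stratum = 2, cfg_hh_per_urban = 1,
                       cfg_pop_per_psu = 30, cfg_random_number = 0.2)
  s <- select_seeds(fr, cfg)
  rng <- gridpsu:::seeded_rng(7)
  ps <- grow_psus(s, partition_regions(s, fr), fr, cfg, rng)
  list(frame = fr, psus = ps, totals = summarize_strata(fr))
}

test_that("strata totals sum eligible cells and split urban/rural", {
  fr <- frame_from(matrix(1, 2, 2),
                   urbanmat = matrix(c(1, 0, 0, 0), 2, 2))
  tot <- summarize_strata(fr)
  expect_equal(tot$str_pop, 4)
  expect_equal(tot$str_u_pop, 1)
  expect_equal(tot$str_r_pop, 3)
  expect_equal(tot$str_cells, 4)

  # no urban layer -> all rural; totals independent of row order
  fr2 <- frame_from(matrix(1:6 / 2, 2, 3))
  tot2 <- summarize_strata(fr2)
  expect_equal(tot2$str_u_pop, 0)
  expect_equal(tot2$str_pop, sum(1:6 / 2))
  expect_equal(summarize_strata(fr2[sample(nrow(fr2)), ]), tot2)
})

test_that("psu_records reconciles with strata totals", {
  run <- make_run()
  rec <- psu_records(run$psus, run$totals)
  expect_equal(rec$psu_pop, rec$psu_r_pop + rec$psu_u_pop)
  expect_equal(rec$str_pop, rec$str_r_pop + rec$str_u_pop)
  for (st in unique(rec$stratum)) {
    sub <- rec[rec$stratum == st, ]
    expect_true(all(sub$psus_in_stratum == nrow(sub)))
    expect_lte(sum(sub$psu_pop), sub$str_pop[1] + 1e-9)
  }
  expect_true(all(rec$U_R %in% c("U", "R")))
})

test_that("written layer round-trips attributes and dissolves geometry", {
  run <- make_run()
  base <- file.path(withr::local_tempdir(), "psu")
  files <- write_psu_layer(run$psus, run$totals, run$frame, base,
                           cfg = NULL, random_number_used = 0.2)
  rec <- psu_records(run$psus, run$totals)
  back <- utils::read.csv(files[["csv"]])
  expect_equal(back, rec)                                  # round-trip oracle

  gj <- jsonlite::fromJSON(paste(readLines(files[["geojson"]]), collapse = ""),
                           simplifyVector = FALSE)
  expect_equal(length(gj$features), nrow(rec))
  props <- gj$features[[1]]$properties
  expect_equal(props$psu_pop, rec$psu_pop[1])
  expect_equal(props$psus_in_stratum, rec$psus_in_stratum[1])
  # planar geometry area = member count x cell area (shoelace on all rings)
  cellA <- 100 * 100
  for (i in seq_along(gj$features)) {
    rings <- gj$features[[i]]$geometry$coordinates
    area <- sum(vapply(rings, function(r) {
      xy <- do.call(rbind, lapply(r, unlist))
      n <- nrow(xy)
      sum(xy[-n, 1] * xy[-1, 2] - xy[-1, 1] * xy[-n, 2]) / 2
    }, numeric(1)))
    expect_equal(area, run$psus$psus$n_cells[rec$PSUid[i]] * cellA)
  }
  expect_true(any(grepl("random_number_used = 0.2", readLines(files[["sidecar"]]))))
})

test_that("single cells and merged neighbours produce clean polygons", {
  geom <- list(n_rows = 3L, n_cols = 3L, origin_x = 0, origin_y = 300,
               cell_width = 100, cell_height = 100)
  # single cell -> one rectangular ring matching the cell bounds
  rings <- gridpsu:::psu_polygon(1L, 1L, geom)
  expect_equal(length(rings), 1L)
  expect_equal(nrow(rings[[1]]), 5L)
  expect_equal(range(rings[[1]][, 1]), c(100, 200))
  expect_equal(range(rings[[1]][, 2]), c(100, 200))
  # two 4-adjacent cells -> one merged ring, no interior boundary
  rings2 <- gridpsu:::psu_polygon(c(1L, 1L), c(1L, 2L), geom)
  expect_equal(length(rings2), 1L)
  expect_equal(range(rings2[[1]][, 1]), c(100, 300))
  # ring with a hole: 8 cells surrounding a missing centre
  rc <- expand.grid(r = 0:2, c = 0:2)
  rc <- rc[!(rc$r == 1 & rc$c == 1), ]
  rings3 <- gridpsu:::psu_polygon(as.integer(rc$r), as.integer(rc$c), geom)
  expect_equal(length(rings3), 2L)
  a <- function(rg) { n <- nrow(rg)
    sum(rg[-n, 1] * rg[-1, 2] - rg[-1, 1] * rg[-n, 2]) / 2 }
  expect_gt(a(rings3[[1]]), 0)   # exterior first, CCW
  expect_lt(a(rings3[[2]]), 0)   # hole CW
  expect_equal(a(rings3[[1]]) + a(rings3[[2]]), 8 * 100 * 100)
})

test_that("shapefile output is refused with guidance", {
  run <- make_run()
  expect_error(write_psu_layer(run$psus, run$totals, run$frame,
                               tempfile(), format = "shapefile"),
               "not supported")
})
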