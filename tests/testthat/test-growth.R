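# Voronoi partition and randomized dilation growth

growth_cfg <- function(pop_per_psu, max_size = Inf, growth = TRUE)
  sample_config(cfg_hh_per_stratum = 1, cfg_hh_per_urban = 1,
                cfg_pop_per_psu = pop_per_psu, cfg_psu_growth = growth,
                cfg_max_psu_size = max_size)

test_that("partition assigns nearest seed within stratum, ties to lower id", {
  fr <- frame_from(matrix(1, 1, 9))
  s <- seed_set_from(fr, fr$cell_id[c(1, 9)])
  reg <- partition_regions(s, fr)
  expect_equal(sum(reg$assignment == 1), 5L)  # midpoint tie -> lower psu_id
  expect_equal(sum(reg$assignment == 2), 4L)

  # one seed per stratum owns the whole stratum
  st <- matrix(rep(1:2, each = 8), 4, 4)
  fr2 <- frame_from(matrix(1, 4, 4), st)
  s2 <- seed_set_from(fr2, c(fr2$cell_id[fr2$stratum_id == 1][1],
                             fr2$cell_id[fr2$stratum_id == 2][1]))
  reg2 <- partition_regions(s2, fr2)
  expect_true(all(reg2$assignment[fr2$stratum_id == 1] == 1))
  expect_true(all(reg2$assignment[fr2$stratum_id == 2] == 2))

  # a cell equidistant to a nearer foreign-stratum seed stays in its stratum
  expect_true(all(fr2$stratum_id[reg2$assignment == 1] == 1))
})

test_that("unit-population growth reaches the exact target cell count", {
  fr <- frame_from(matrix(1, 5, 5))
  centre <- fr$cell_id[fr$row == 2 & fr$col == 2]
  s <- seed_set_from(fr, centre)
  reg <- partition_regions(s, fr)
  ps <- grow_psus(s, reg, fr, growth_cfg(5), gridpsu:::seeded_rng(1))
  expect_equal(ps$psus$n_cells, 5L)
  expect_equal(ps$psus$psu_pop, 5)
  mm <- match(ps$members[[1]], fr$cell_id)
  expect_true(is_4_connected(fr$row[mm], fr$col[mm]))
  expect_true(centre %in% ps$members[[1]])
})

test_that("growth off, immediate stop, and area cap each leave single cells", {
  fr <- frame_from(matrix(2, 4, 4))
  s <- seed_set_from(fr, fr$cell_id[c(1, 16)])
  reg <- partition_regions(s, fr)
  # growth disabled
  ps <- grow_psus(s, reg, fr, growth_cfg(100, growth = FALSE),
                  gridpsu:::seeded_rng(1))
  expect_equal(ps$psus$n_cells, c(1L, 1L))
  # seed already at/above the population target
  ps2 <- grow_psus(s, reg, fr, growth_cfg(2), gridpsu:::seeded_rng(1))
  expect_equal(ps2$psus$n_cells, c(1L, 1L))
  # area cap of one cell (100 m cell = 0.01 km^2)
  ps3 <- grow_psus(s, reg, fr, growth_cfg(100, max_size = 0.01),
                   gridpsu:::seeded_rng(1))
  expect_equal(ps3$psus$n_cells, c(1L, 1L))
  expect_true(all(ps3$psus$below_target))
})

test_that("PSUs are disjoint, contiguous, contained, and bounded overshoot", {
  set.seed(77)
  for (i in 1:25) {
    spec <- fixture_spec(12, 12, sample(c("blobs", "gradient", "uniform"), 1),
                         strata_layout = sample(1:2, 2, replace = TRUE),
                         seed = i)
    pop <- make_population(spec)
    fr <- build_frame(pop, make_strata(spec), NULL, growth_cfg(1))
    cfg <- growth_cfg(sample(c(10, 30, 60), 1),
                      max_size = sample(c(Inf, 0.05), 1))
    cfg$cfg_hh_per_stratum <- 2; cfg$cfg_hh_per_urban <- 1   # n_k = 2
    s <- select_seeds(fr, cfg, gridpsu:::seeded_rng(100 + i))
    reg <- partition_regions(s, fr)
    ps <- grow_psus(s, reg, fr, cfg, gridpsu:::seeded_rng(200 + i))
    all_members <- unlist(ps$members)
    expect_false(anyDuplicated(all_members) > 0)             # disjoint
    for (k in seq_along(ps$members)) {
      mm <- match(ps$members[[k]], fr$cell_id)
      expect_true(is_4_connected(fr$row[mm], fr$col[mm]))
      expect_true(all(reg$assignment[mm] == k))              # Voronoi + stratum
      expect_true(all(fr$stratum_id[mm] == ps$psus$stratum_id[k]))
      overshoot <- ps$psus$psu_pop[k] - cfg$cfg_pop_per_psu
      expect_lt(overshoot, max(fr$population[mm]))           # one-cell bound
      expect_equal(ps$psus$psu_pop[k], sum(fr$population[mm]))
      expect_equal(ps$psus$psu_pop[k],
                   ps$psus$psu_u_pop[k] + ps$psus$psu_r_pop[k])
    }
  }
})

test_that("growth is reproducible under a fixed master random number", {
  spec <- fixture_spec(14, 14, "blobs", strata_layout = c(2, 1), seed = 3)
  fr <- build_frame(make_population(spec), make_strata(spec), NULL,
                    growth_cfg(1))
  cfg <- sample_config(cfg_hh_per_stratum = 78, cfg_hh_per_urban = 26,
                       cfg_pop_per_psu = 40, cfg_random_number = 0.42)
  run_once <- function() {
    s <- select_seeds(fr, cfg)
    rng <- gridpsu:::seeded_rng(
      gridpsu:::master_seed_from_random_number(s$random_number_used))
    grow_psus(s, partition_regions(s, fr), fr, cfg, rng)
  }
  expect_identical(run_once(), run_once())
})
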