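# Seeded synthetic fixtures emulating the structure of real inputs: a
# population surface (uniform, smooth gradient, or clustered Gaussian
# "blob" settlements on a sparse rural background), a rectangular block
# partition of strata, and an urban mask from the density-threshold rule.
# Everything is a pure function of the spec (seeded determinism), so fixtures
# are generated at test time rather than stored.

#' Specification for a synthetic fixture triplet
#'
#' @param n_rows,n_cols grid dimensions.
#' @param surface `"uniform"`, `"gradient"` or `"blobs"`.
#' @param value mean persons per cell for the uniform surface and the
#'   gradient's midpoint (default 5, a plausible rural 100 m-cell density).
#' @param blob_count number of Gaussian settlement bumps (default 5).
#' @param blob_scale bump standard deviation in cells (default 1/10 of the
#'   short grid side).
#' @param blob_peak peak persons per cell at a bump centre (default 50,
#'   giving an urban/rural contrast like a small-town landscape).
#' @param strata_layout integer c(r, c): split the grid into an r x c block
#'   partition of strata, ids 1..r*c.
#' @param urban_rule density-threshold fraction for the urban mask (0 = no
#'   urban cells).
#' @param nodata_fraction proportion of cells knocked out as missing.
#' @param cell_size cell side in map units (metres), default 100.
#' @param seed integer RNG seed.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_rows = 20, n_cols = 20,
                         surface = c("uniform", "gradient", "blobs"),
                         value = 5, blob_count = 5, blob_scale = NULL,
                         blob_peak = 50,
                         strata_layout = c(1, 1), urban_rule = 0,
                         nodata_fraction = 0, cell_size = 100, seed = 1L) {
  surface <- match.arg(surface)
  stopifnot(n_rows >= 1, n_cols >= 1, urban_rule >= 0, urban_rule <= 1,
            nodata_fraction >= 0, nodata_fraction <= 1,
            length(strata_layout) == 2, all(strata_layout >= 1))
  structure(list(n_rows = n_rows, n_cols = n_cols, surface = surface,
                 value = value, blob_count = blob_count,
                 blob_scale = blob_scale %||% max(1, min(n_rows, n_cols) / 10),
                 blob_peak = blob_peak,
                 strata_layout = as.integer(strata_layout),
                 urban_rule = urban_rule,
                 nodata_fraction = nodata_fraction,
                 cell_size = cell_size, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic population grid
#'
#' Deterministic given `spec$seed`. The uniform surface is a constant;
#' the gradient ramps linearly west to east around `spec$value`; the blobs
#' surface is a sparse random rural background plus `blob_count` Gaussian
#' bumps at seeded random centres (truncated at the grid edge).
#'
#' @param spec a [fixture_spec()].
#' @return a `pop_grid`.
#' @export
make_population <- function(spec) {
  rng <- seeded_rng(spec$seed)
  nr <- spec$n_rows; nc <- spec$n_cols
  m <- switch(spec$surface,
    uniform = matrix(spec$value, nr, nc),
    gradient = matrix(rep(seq(0.1, 2 * spec$value, length.out = nc), each = nr),
                      nr, nc),
    blobs = {
      base <- matrix(0.05 * spec$value * round(matrix(rng$runif(nr * nc), nr)
                                               < 0.5), nr, nc)
      rc <- matrix(rng$runif(2L * spec$blob_count), ncol = 2)
      cr <- 0.5 + rc[, 1] * (nr - 1); cc <- 0.5 + rc[, 2] * (nc - 1)
      rows <- row(base) - 0.5; cols <- col(base) - 0.5
      for (b in seq_len(spec$blob_count)) {
        d2 <- (rows - cr[b])^2 + (cols - cc[b])^2
        base <- base + spec$blob_peak * exp(-d2 / (2 * spec$blob_scale^2))
      }
      base
    })
  if (spec$nodata_fraction > 0) {
    u <- rng$runif(nr * nc)
    m[matrix(u < spec$nodata_fraction, nr, nc)] <- NA
  }
  pop_grid(m, origin_x = 0, origin_y = nr * spec$cell_size,
           cell_width = spec$cell_size, crs_label = "synthetic/metres")
}

#' Generate the block-partition strata grid for a fixture
#'
#' Splits the grid into an r x c rectangular block partition with stratum
#' ids 1..r*c assigned row-major (north-west block is 1).
#'
#' @param spec a [fixture_spec()].
#' @return a `zone_grid` aligned with [make_population()] output.
#' @export
make_strata <- function(spec) {
  nr <- spec$n_rows; nc <- spec$n_cols
  br <- spec$strata_layout[1]; bc <- spec$strata_layout[2]
  ri <- pmin(br, 1L + ((seq_len(nr) - 1L) * br) %/% nr)
  ci <- pmin(bc, 1L + ((seq_len(nc) - 1L) * bc) %/% nc)
  m <- outer(ri, ci, function(a, b) (a - 1L) * bc + b)
  zone_grid(m, origin_x = 0, origin_y = nr * spec$cell_size,
            cell_width = spec$cell_size, crs_label = "synthetic/metres")
}

#' Generate the urban mask for a fixture
#'
#' Applies the density-threshold rule ([classify_urban_by_density()]) at
#' `spec$urban_rule`; a rule of 0 yields no urban cells.
#'
#' @param spec a [fixture_spec()].
#' @param pop the matching population grid.
#' @return a binary `zone_grid`.
#' @export
make_urban <- function(spec, pop) {
  if (spec$urban_rule <= 0) {
    u <- ifelse(is.na(pop$values), NA_real_, 0)
    return(zone_grid(matrix(u, nrow = pop$n_rows),
                     origin_x = pop$origin_x, origin_y = pop$origin_y,
                     cell_width = pop$cell_width,
                     cell_height = pop$cell_height,
                     crs_label = pop$crs_label))
  }
  classify_urban_by_density(pop, spec$urban_rule)$urban
}

#' Materialize a fixture triplet as ESRI ASCII grid files
#'
#' Writes `population.asc`, `strata.asc` and `urban.asc` (plus `.crs`
#' sidecars) into `dir`, exercising the full file I/O path.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return named character vector of the three paths, invisibly.
#' @export
write_fixture_suite <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pop <- make_population(spec)
  paths <- c(population = file.path(dir, "population.asc"),
             strata = file.path(dir, "strata.asc"),
             urban = file.path(dir, "urban.asc"))
  write_asc_grid(pop, paths["population"])
  write_asc_grid(make_strata(spec), paths["strata"])
  write_asc_grid(make_urban(spec, pop), paths["urban"])
  invisible(paths)
}
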