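#' Sampling configuration
#'
#' Collects every `cfg_*` parameter governing a sampling run. Defaults
#' reflect a typical two-stage cluster household survey; all counts are
#' positive and `cfg_random_number`, when supplied, must lie in [0, 1) (it
#' is the recorded random start that reproduces a previous sample).
#'
#' @param cfg_hh_per_stratum households to sample per stratum (also the
#'   minimum per urban/rural sub-domain when `cfg_sample_rururb` is on).
#' @param cfg_hh_per_urban households sampled per urban PSU.
#' @param cfg_hh_per_rural households sampled per rural PSU; defaults to the
#'   urban value.
#' @param cfg_pop_per_psu target population per PSU (persons); growth stops
#'   once a PSU reaches it.
#' @param cfg_psu_growth grow PSUs beyond their seed cell?
#' @param cfg_max_psu_size maximum PSU area in km^2 (`Inf` = uncapped).
#' @param cfg_min_pop_per_cell cells below this population are excluded from
#'   the sample frame.
#' @param cfg_desired_cell_size integer aggregation factor applied to the
#'   population raster before framing (1 = native resolution).
#' @param cfg_sample_rururb enforce the per-sub-domain household minimum by
#'   urban/rural seed swaps?
#' @param cfg_sample_spatial enforce spatial coverage on a coarse grid?
#' @param cfg_sample_spatial_scale coarse-grid cell side in km.
#' @param cfg_random_number optional recorded random start in [0, 1); when
#'   absent a fresh one is drawn and reported.
#' @param sample_name,output_path naming for output files.
#' @return a validated `sample_config` list.
#' @export
sample_config <- function(cfg_hh_per_stratum,
                          cfg_hh_per_urban,
                          cfg_hh_per_rural = cfg_hh_per_urban,
                          cfg_pop_per_psu,
                          cfg_psu_growth = TRUE,
                          cfg_max_psu_size = Inf,
                          cfg_min_pop_per_cell = 0,
                          cfg_desired_cell_size = 1L,
                          cfg_sample_rururb = FALSE,
                          cfg_sample_spatial = FALSE,
                          cfg_sample_spatial_scale = 20,
                          cfg_random_number = NULL,
                          sample_name = "psu_sample",
                          output_path = ".") {
  chk_pos <- function(x, nm) {
    if (length(x) != 1L || is.na(x) || x <= 0)
      stop(nm, " must be a single positive number")
  }
  chk_pos(cfg_hh_per_stratum, "cfg_hh_per_stratum")
  chk_pos(cfg_hh_per_urban, "cfg_hh_per_urban")
  chk_pos(cfg_hh_per_rural, "cfg_hh_per_rural")
  chk_pos(cfg_pop_per_psu, "cfg_pop_per_psu")
  chk_pos(cfg_max_psu_size, "cfg_max_psu_size")
  chk_pos(cfg_sample_spatial_scale, "cfg_sample_spatial_scale")
  if (cfg_min_pop_per_cell < 0) stop("cfg_min_pop_per_cell must be >= 0")
  if (cfg_desired_cell_size < 1 || cfg_desired_cell_size != round(cfg_desired_cell_size))
    stop("cfg_desired_cell_size must be a positive integer")
  if (!is.null(cfg_random_number)) {
    if (length(cfg_random_number) != 1L || is.na(cfg_random_number) ||
        cfg_random_number < 0 || cfg_random_number >= 1)
      stop("cfg_random_number must lie in [0, 1)")
  }
  structure(list(
    cfg_hh_per_stratum = cfg_hh_per_stratum,
    cfg_hh_per_urban = cfg_hh_per_urban,
    cfg_hh_per_rural = cfg_hh_per_rural,
    cfg_pop_per_psu = cfg_pop_per_psu,
    cfg_psu_growth = isTRUE(cfg_psu_growth),
    cfg_max_psu_size = cfg_max_psu_size,
    cfg_min_pop_per_cell = cfg_min_pop_per_cell,
    cfg_desired_cell_size = as.integer(cfg_desired_cell_size),
    cfg_sample_rururb = isTRUE(cfg_sample_rururb),
    cfg_sample_spatial = isTRUE(cfg_sample_spatial),
    cfg_sample_spatial_scale = cfg_sample_spatial_scale,
    cfg_random_number = cfg_random_number,
    sample_name = sample_name,
    output_path = output_path
  ), class = "sample_config")
}

#' Read a sampling configuration from a flat key=value file
#'
#' Keys are the `cfg_*` parameter names plus the input paths
#' `population_raster`, `strata_raster` (or `strata_geojson` with
#' `strata_label_field`), and optional `urban_raster`. Lines starting with
#' `#` and blank lines are ignored; values are parsed as numbers or
#' TRUE/FALSE where they look like them.
#'
#' @param path config file path.
#' @param overrides named list applied on top of the file's values.
#' @return list with `config` (a `sample_config`) and `inputs` (named paths).
#' @export
read_config_file <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(sub("\\s*=\\s*", "\x01", lines), "\x01", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  vals <- lapply(kv, function(p) parse_config_value(trimws(p[2])))
  names(vals) <- trimws(vapply(kv, `[`, "", 1L))
  vals[names(overrides)] <- overrides
  input_keys <- c("population_raster", "strata_raster", "strata_geojson",
                  "strata_label_field", "urban_raster")
  inputs <- vals[intersect(input_keys, names(vals))]
  cfg_args <- vals[setdiff(names(vals), input_keys)]
  known <- names(formals(sample_config))
  unknown <- setdiff(names(cfg_args), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  missing_req <- setdiff(c("cfg_hh_per_stratum", "cfg_hh_per_urban", "cfg_pop_per_psu"),
                         names(cfg_args))
  if (length(missing_req))
    stop("missing required config parameter(s): ", paste(missing_req, collapse = ", "))
  list(config = do.call(sample_config, cfg_args), inputs = inputs)
}

parse_config_value <- function(x) {
  if (toupper(x) %in% c("TRUE", "FALSE")) return(as.logical(toupper(x)))
  n <- suppressWarnings(as.numeric(x))
  if (!is.na(n)) return(n)
  x
}

# ---- deterministic randomness --------------------------------------------
# All stochastic steps downstream of seed selection draw from one stream
# seeded by the run's master random number, so a single recorded value
# reproduces the whole sample. The stream is kept separate from the caller's
# .Random.seed.

master_seed_from_random_number <- function(r) {
  as.integer(floor(r * 2147483646)) + 1L
}

seeded_rng <- function(seed) {
  e <- new.env(parent = emptyenv())
  swap_in <- function() {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    if (is.null(e$state)) set.seed(as.integer(seed))
    else assign(".Random.seed", e$state, envir = globalenv())
    old
  }
  swap_out <- function(old) {
    e$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
  with_stream <- function(expr) {
    old <- swap_in()
    on.exit(swap_out(old))
    expr
  }
  structure(list(
    runif = function(n = 1L) with_stream(stats::runif(n)),
    pick = function(x) {
      if (length(x) == 0L) stop("cannot pick from an empty set")
      if (length(x) == 1L) return(x)
      x[with_stream(sample.int(length(x), 1L))]
    }
  ), class = "seeded_rng")
}
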