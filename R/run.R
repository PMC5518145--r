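#' Run the full sampling pipeline
#'
#' Single entry point wiring config -> frame -> seed selection -> sub-domain
#' oversample -> spatial oversample -> growth -> output, in that fixed
#' order. All randomness flows from one master random number (drawn unless
#' `cfg_random_number` is set) which is printed, written to the manifest and
#' the sidecar, and reproduces the whole run byte-for-byte when passed back.
#'
#' @param config a `sample_config`, or the path to a flat key=value config
#'   file (see [read_config_file()]) that also names the inputs.
#' @param inputs named list/vector of input paths — `population_raster`
#'   (ESRI ASCII grid), `strata_raster` or `strata_geojson` (+
#'   `strata_label_field`), optional `urban_raster`. Ignored when `config`
#'   is a file that names them.
#' @param overrides named list of config overrides (file-based configs only).
#' @param out_dir output directory; defaults to the config's `output_path`.
#' @param quiet suppress progress messages.
#' @return a `run_manifest` (invisibly): resolved config, input checksums,
#'   `random_number_used`, per-stage counts, warnings, and output file paths.
#' @export
run_sample <- function(config, inputs = NULL, overrides = list(),
                       out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) {
    parsed <- read_config_file(config, overrides)
    cfg <- parsed$config
    inputs <- parsed$inputs
  } else cfg <- config
  say <- function(...) if (!quiet) message(...)
  inputs <- as.list(inputs)
  if (is.null(inputs$population_raster))
    stop("config error: population_raster is required")
  if (is.null(inputs$strata_raster) && is.null(inputs$strata_geojson))
    stop("config error: a strata layer (strata_raster or strata_geojson) is required")
  warnings_seen <- character(0)

  pop <- load_population_raster(inputs$population_raster)
  if (cfg$cfg_desired_cell_size > 1L) {
    pop <- aggregate_cells(pop, cfg$cfg_desired_cell_size)
    say("aggregated cells by factor ", cfg$cfg_desired_cell_size)
  }
  strata <- if (!is.null(inputs$strata_raster)) {
    s <- load_zone_raster(inputs$strata_raster)
    if (cfg$cfg_desired_cell_size > 1L)
      stop("config error: pre-rasterized strata cannot be used with ",
           "cfg_desired_cell_size > 1; supply strata_geojson instead")
    s
  } else rasterize_zones(inputs$strata_geojson, pop,
                         inputs$strata_label_field %||% "id")
  urban <- if (!is.null(inputs$urban_raster)) {
    u <- load_zone_raster(inputs$urban_raster)
    if (cfg$cfg_desired_cell_size > 1L)
      stop("config error: pre-rasterized urban mask cannot be used with ",
           "cfg_desired_cell_size > 1")
    u
  } else NULL
  if (cfg$cfg_sample_rururb && is.null(urban))
    stop("config error: cfg_sample_rururb requires urban_raster")

  frame <- build_frame(pop, strata, urban, cfg)
  say("frame: ", nrow(frame), " eligible cells in ",
      length(unique(frame$stratum_id)), " strata")

  seeds <- select_seeds(frame, cfg)
  r <- seeds$random_number_used
  say(sprintf("random number used: %.15f (record to reproduce this sample)", r))
  rng <- seeded_rng(master_seed_from_random_number(r))

  n_swaps <- c(subdomain = 0L, spatial = 0L)
  if (cfg$cfg_sample_rururb) {
    seeds <- enforce_subdomain_minimum(seeds, frame, cfg, rng)
    n_swaps["subdomain"] <- nrow(attr(seeds, "swap_log"))
    say("sub-domain adjustment: ", n_swaps["subdomain"], " swap(s)")
  }
  if (cfg$cfg_sample_spatial) {
    coarse <- build_coarse_grid(frame, cfg$cfg_sample_spatial_scale)
    seeds <- withCallingHandlers(
      enforce_spatial_coverage(seeds, frame, coarse, rng),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    n_swaps["spatial"] <- sum(attr(seeds, "swap_log")$reason == "spatial")
    say("spatial adjustment: ", n_swaps["spatial"], " swap(s)")
  }

  regions <- partition_regions(seeds, frame)
  psus <- grow_psus(seeds, regions, frame, cfg, rng)
  say("grew ", nrow(psus$psus), " PSUs (median population ",
      round(stats::median(psus$psus$psu_pop), 1), ")")

  totals <- summarize_strata(frame)
  out_dir <- out_dir %||% cfg$output_path
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(out_dir, cfg$sample_name)
  files <- write_psu_layer(psus, totals, frame, base, cfg = cfg,
                           random_number_used = r)

  manifest <- list(
    config = cfg[setdiff(names(cfg), "cfg_random_number")],
    inputs = lapply(inputs, function(p)
      if (is.character(p) && file.exists(p))
        list(path = p, md5 = unname(tools::md5sum(p))) else p),
    random_number_used = r,
    counts = list(eligible_cells = nrow(frame),
                  strata = length(unique(frame$stratum_id)),
                  seeds = nrow(seeds$seeds),
                  swaps = as.list(n_swaps),
                  psus = nrow(psus$psus),
                  psus_below_target = sum(psus$psus$below_target)),
    warnings = warnings_seen,
    outputs = as.list(files)
  )
  manifest_path <- paste0(base, "_manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE), manifest_path)
  manifest$outputs$manifest <- manifest_path
  structure(c(manifest, list(frame = frame, seeds = seeds, psus = psus,
                             strata_totals = totals)),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  cat(sprintf("  random number used: %.15f\n", x$random_number_used))
  cat(sprintf("  eligible cells: %d; seeds: %d; PSUs: %d (%d below target)\n",
              x$counts$eligible_cells, x$counts$seeds, x$counts$psus,
              x$counts$psus_below_target))
  cat("  outputs:", paste(unlist(x$outputs), collapse = ", "), "\n")
  invisible(x)
}
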