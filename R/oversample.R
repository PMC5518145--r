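# Post-selection seed adjustments. Both adjustments swap seeds one-for-one
# within a stratum, so every stratum keeps exactly its allocated n_k PSUs.
# Fixed order in the pipeline: selection -> sub-domain minimum -> spatial
# coverage.

#' Enforce the urban/rural sub-domain household minimum
#'
#' Urban and rural populations treated as sub-domains (not strata) must each
#' yield at least `cfg_hh_per_stratum` sampled households study-wide
#' (urban seeds x `cfg_hh_per_urban`; rural seeds x `cfg_hh_per_rural`).
#' While one sub-domain falls short, the next non-seed cell of that
#' sub-domain in serpentine order — from any stratum — becomes a seed and
#' one randomly chosen seed of the opposite sub-domain in the same stratum
#' is dropped. Per-stratum PSU counts are unchanged; the loop ends when both
#' sub-domains meet the minimum. If both are deficient (pathological),
#' urban is corrected first.
#'
#' @param seeds a `seed_set`.
#' @param frame a `grid_frame` with urban classification.
#' @param cfg a [sample_config()] with `cfg_sample_rururb = TRUE`.
#' @param rng a `seeded_rng` for the random drop.
#' @return the adjusted `seed_set`, with a `swap_log` attribute (data.frame
#'   of added/dropped cells).
#' @export
enforce_subdomain_minimum <- function(seeds, frame, cfg, rng) {
  if (!cfg$cfg_sample_rururb) return(seeds)
  sdf <- seeds$seeds
  log <- list()
  implied <- function(sdf, urb) {
    n <- sum(sdf$urban == urb)
    n * (if (urb) cfg$cfg_hh_per_urban else cfg$cfg_hh_per_rural)
  }
  deficient <- function(sdf) {
    if (implied(sdf, TRUE) < cfg$cfg_hh_per_stratum) return(TRUE)   # urban first
    if (implied(sdf, FALSE) < cfg$cfg_hh_per_stratum) return(FALSE)
    NULL
  }
  repeat {
    need <- deficient(sdf)
    if (is.null(need)) break
    if (!any(frame$urban == need))
      stop("sub-domain oversampling infeasible: frame has no ",
           if (need) "urban" else "rural", " cells")
    cand <- frame[frame$urban == need & !(frame$cell_id %in% sdf$cell_id), ,
                  drop = FALSE]
    added <- FALSE
    for (i in seq_len(nrow(cand))) {          # serpentine order from index 0
      st <- cand$stratum_id[i]
      victims <- which(sdf$stratum_id == st & sdf$urban != need)
      if (length(victims) == 0L) next
      drop_i <- if (length(victims) == 1L) victims else
        victims[match(rng$pick(sdf$cell_id[victims]), sdf$cell_id[victims])]
      log[[length(log) + 1L]] <- data.frame(
        reason = "subdomain", added_cell = cand$cell_id[i],
        dropped_cell = sdf$cell_id[drop_i], stratum_id = st)
      sdf[drop_i, ] <- data.frame(cell_id = cand$cell_id[i],
                                  stratum_id = st, urban = need)
      added <- TRUE
      break
    }
    if (!added)
      stop("sub-domain oversampling infeasible: no stratum holds both a ",
           "candidate ", if (need) "urban" else "rural",
           " cell and an opposite-sub-domain seed to swap out")
  }
  out <- new_seed_set(sdf, seeds$n_per_stratum, seeds$random_number_used)
  attr(out, "swap_log") <- if (length(log)) do.call(rbind, log) else
    data.frame(reason = character(), added_cell = integer(),
               dropped_cell = integer(), stratum_id = integer())
  out
}

#' Overlay a coarse grid for spatial oversampling
#'
#' Builds the coarse grid at `scale_km` against which spatial coverage is
#' enforced. The representative fine-cell ground size is taken from the
#' frame's centroid cell (correcting for degree cells shrinking toward the
#' poles); `cells_per_side = round(scale_km * 1000 / side_m)`, floored at 1.
#' Coarse cells tile the extent from the raster origin (north-west corner),
#' and each frame cell maps to a coarse id by integer division of its
#' row/col indices.
#'
#' @param frame a `grid_frame`.
#' @param scale_km coarse cell side in km.
#' @return a `coarse_grid`: list with `scale_km`, `cells_per_side`, and
#'   `coarse_id` (integer per frame row, aligned with `frame`).
#' @export
build_coarse_grid <- function(frame, scale_km) {
  if (scale_km <= 0) stop("scale_km must be positive")
  g <- frame_geometry(frame)
  sz <- centroid_cell_size(structure(g, class = "pop_grid"))
  side_m <- sqrt(sz$side_x_m * sz$side_y_m)
  cps <- max(1L, as.integer(round(scale_km * 1000 / side_m)))
  n_ccols <- ceiling(g$n_cols / cps)
  cid <- (frame$row %/% cps) * n_ccols + (frame$col %/% cps) + 1L
  structure(list(scale_km = scale_km, cells_per_side = cps,
                 coarse_id = as.integer(cid)),
            class = "coarse_grid")
}

#' Enforce spatial coverage: at least one seed per coarse cell
#'
#' Every coarse grid cell containing at least one eligible frame cell should
#' contain a seed, so the sample is representative of space as well as
#' population. Empty coarse cells are visited in coarse-id order: the first
#' frame cell (serpentine order) inside the coarse cell is added as a seed,
#' and one randomly chosen seed from the same stratum and sub-domain is
#' dropped — never a seed that is its own coarse cell's only seed (that
#' would just move the hole). An insertion with no valid paired drop is
#' skipped and logged rather than failing.
#'
#' @param seeds a `seed_set`.
#' @param frame a `grid_frame`.
#' @param coarse a [build_coarse_grid()] result.
#' @param rng a `seeded_rng` for the random drop.
#' @return the adjusted `seed_set` with a `swap_log` attribute.
#' @export
enforce_spatial_coverage <- function(seeds, frame, coarse, rng) {
  sdf <- seeds$seeds
  cid <- coarse$coarse_id
  log <- list()
  seed_coarse <- function(sdf) cid[match(sdf$cell_id, frame$cell_id)]
  for (cc in sort(unique(cid))) {
    sc <- seed_coarse(sdf)
    if (any(sc == cc)) next
    in_cc <- which(cid == cc & !(frame$cell_id %in% sdf$cell_id))
    if (length(in_cc) == 0L) next
    cand <- in_cc[1L]                      # first in serpentine order
    st <- frame$stratum_id[cand]; urb <- frame$urban[cand]
    counts <- table(sc)
    victims <- which(sdf$stratum_id == st & sdf$urban == urb &
                       counts[as.character(sc)] > 1L)
    if (length(victims) == 0L) {
      log[[length(log) + 1L]] <- data.frame(
        reason = "spatial_skipped", added_cell = NA_integer_,
        dropped_cell = NA_integer_, stratum_id = st, coarse_id = cc)
      warning("spatial coverage: coarse cell ", cc,
              " left unseeded (no valid seed to drop in stratum ", st,
              ", sub-domain ", if (urb) "urban" else "rural", ")")
      next
    }
    drop_i <- if (length(victims) == 1L) victims else
      victims[match(rng$pick(sdf$cell_id[victims]), sdf$cell_id[victims])]
    log[[length(log) + 1L]] <- data.frame(
      reason = "spatial", added_cell = frame$cell_id[cand],
      dropped_cell = sdf$cell_id[drop_i], stratum_id = st, coarse_id = cc)
    sdf[drop_i, ] <- data.frame(cell_id = frame$cell_id[cand],
                                stratum_id = st, urban = urb)
  }
  out <- new_seed_set(sdf, seeds$n_per_stratum, seeds$random_number_used)
  attr(out, "swap_log") <- if (length(log)) do.call(rbind, log) else
    data.frame(reason = character(), added_cell = integer(),
               dropped_cell = integer(), stratum_id = integer(),
               coarse_id = integer())
  out
}
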