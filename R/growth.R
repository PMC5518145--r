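#' Partition eligible cells into per-seed growth regions
#'
#' Assigns every eligible cell to the nearest seed of its own stratum
#' (planar Euclidean distance between cell centres, ties to the lowest PSU
#' id) — a Voronoi partition computed within each stratum. Growth is later
#' confined to these regions, which makes PSUs contiguous, non-overlapping
#' and unable to cross stratum boundaries. PSU ids are assigned 1..n in
#' (stratum, serpentine) order of the seed cells, so they are reproducible.
#'
#' @param seeds a `seed_set`.
#' @param frame a `grid_frame`.
#' @return a `growth_region`: list with `psus` (data.frame `psu_id`,
#'   `seed_cell`, `stratum_id`, `urban`) and `assignment` (owning `psu_id`
#'   for each frame row).
#' @export
partition_regions <- function(seeds, frame) {
  m <- match(seeds$seeds$cell_id, frame$cell_id)
  if (anyNA(m)) stop("seed cell not present in frame")
  ord <- order(seeds$seeds$stratum_id, frame$serpentine_index[m])
  psus <- data.frame(psu_id = seq_along(ord),
                     seed_cell = seeds$seeds$cell_id[ord],
                     stratum_id = seeds$seeds$stratum_id[ord],
                     urban = seeds$seeds$urban[ord])
  sm <- match(psus$seed_cell, frame$cell_id)
  assignment <- integer(nrow(frame))
  for (st in unique(psus$stratum_id)) {
    rows <- which(frame$stratum_id == st)
    sid <- which(psus$stratum_id == st)
    dx <- outer(frame$x_center[rows], frame$x_center[sm[sid]], "-")
    dy <- outer(frame$y_center[rows], frame$y_center[sm[sid]], "-")
    d2 <- dx * dx + dy * dy
    nearest <- max.col(-d2, ties.method = "first")   # lowest psu_id on ties
    assignment[rows] <- psus$psu_id[sid][nearest]
  }
  structure(list(psus = psus, assignment = assignment),
            class = "growth_region")
}

#' Grow PSUs around their seeds by randomized dilation
#'
#' Starting from each seed cell, PSUs are enlarged one cell at a time in
#' round-robin passes over PSU id: each pass, every unfinished PSU adds one
#' cell chosen uniformly at random from the 4-neighbour frontier of its
#' current members, restricted to cells of its own growth region. A PSU is
#' finished when its population reaches `cfg_pop_per_psu`, its area reaches
#' `cfg_max_psu_size` km^2, or its frontier is exhausted (in which case it
#' is flagged `below_target`). With `cfg_psu_growth = FALSE` every PSU is
#' its seed cell alone. Ineligible cells (excluded from the frame) are never
#' added; holes they leave inside a PSU's footprint do not break the
#' 4-connectivity of the members themselves.
#'
#' @param seeds a `seed_set`.
#' @param regions a [partition_regions()] result.
#' @param frame a `grid_frame`.
#' @param cfg a [sample_config()].
#' @param rng a `seeded_rng` driving the frontier choice.
#' @return a `psu_set`: list with `psus` (data.frame of per-PSU attributes)
#'   and `members` (list of member `cell_id` vectors, indexed by psu_id).
#' @export
grow_psus <- function(seeds, regions, frame, cfg, rng) {
  psus <- regions$psus
  n_psu <- nrow(psus)
  g <- frame_geometry(frame)
  cell_area <- frame_cell_area_km2(frame)
  # frame-row lookup by grid position
  pos_of <- function(r, c) r * g$n_cols + c + 1L
  lookup <- integer(g$n_rows * g$n_cols)
  lookup[pos_of(frame$row, frame$col)] <- seq_len(nrow(frame))
  neighbours <- function(i) {
    r <- frame$row[i]; c <- frame$col[i]
    cand <- rbind(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))
    ok <- cand[, 1] >= 0L & cand[, 1] < g$n_rows &
          cand[, 2] >= 0L & cand[, 2] < g$n_cols
    idx <- lookup[pos_of(cand[ok, 1], cand[ok, 2])]
    idx[idx > 0L]
  }
  seed_row <- match(psus$seed_cell, frame$cell_id)
  members <- lapply(seed_row, function(i) i)          # frame row indices
  pop <- frame$population[seed_row]
  frontier <- vector("list", n_psu)
  finished <- logical(n_psu)
  check_done <- function(k) {
    pop[k] >= cfg$cfg_pop_per_psu ||
      length(members[[k]]) * cell_area >= cfg$cfg_max_psu_size
  }
  for (k in seq_len(n_psu)) {
    frontier[[k]] <- setdiff(
      neighbours(seed_row[k])[regions$assignment[neighbours(seed_row[k])] == k],
      members[[k]])
    finished[k] <- !cfg$cfg_psu_growth || check_done(k) ||
      length(frontier[[k]]) == 0L
  }
  while (cfg$cfg_psu_growth && !all(finished)) {
    for (k in which(!finished)) {
      fr <- frontier[[k]]
      if (length(fr) == 0L) { finished[k] <- TRUE; next }
      add <- rng$pick(fr)
      members[[k]] <- c(members[[k]], add)
      pop[k] <- pop[k] + frame$population[add]
      nb <- neighbours(add)
      nb <- nb[regions$assignment[nb] == k]
      frontier[[k]] <- setdiff(unique(c(fr, nb)), members[[k]])
      if (check_done(k) || length(frontier[[k]]) == 0L) finished[k] <- TRUE
    }
  }
  u_pop <- vapply(members, function(mm)
    sum(frame$population[mm][frame$urban[mm]]), numeric(1))
  out <- data.frame(
    psu_id = psus$psu_id,
    seed_cell = psus$seed_cell,
    stratum_id = psus$stratum_id,
    urban = psus$urban,
    psu_pop = pop,
    psu_u_pop = u_pop,
    psu_r_pop = pop - u_pop,
    n_cells = lengths(members),
    area_km2 = lengths(members) * cell_area,
    centroid_x = frame$x_center[seed_row],
    centroid_y = frame$y_center[seed_row],
    below_target = pop < cfg$cfg_pop_per_psu
  )
  if (cfg$cfg_psu_growth && any(out$below_target))
    message(sum(out$below_target),
            " PSU(s) stopped below cfg_pop_per_psu (area cap or exhausted region)")
  structure(list(psus = out,
                 members = lapply(members, function(mm) frame$cell_id[mm])),
            class = "psu_set")
}

#' @export
print.psu_set <- function(x, ...) {
  cat(sprintf("<psu_set> %d PSUs, median population %.1f, mean cells %.1f\n",
              nrow(x$psus), stats::median(x$psus$psu_pop),
              mean(x$psus$n_cells)))
  invisible(x)
}
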