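# In-code fixtures: tiny grids and frames built directly from matrices.

`%||%` <- function(a, b) if (is.null(a)) b else a

grid_from <- function(m, cell = 100, crs = "synthetic/metres") {
  pop_grid(m, origin_x = 0, origin_y = nrow(as.matrix(m)) * cell,
           cell_width = cell, crs_label = crs)
}

zones_from <- function(m, cell = 100, crs = "synthetic/metres") {
  zone_grid(m, origin_x = 0, origin_y = nrow(as.matrix(m)) * cell,
            cell_width = cell, crs_label = crs)
}

# frame straight from matrices; strata/urban default to one stratum, all rural
frame_from <- function(popmat, stratmat = NULL, urbanmat = NULL,
                       min_pop = 0, cell = 100) {
  popmat <- as.matrix(popmat)
  if (is.null(stratmat)) stratmat <- matrix(1, nrow(popmat), ncol(popmat))
  cfg <- sample_config(cfg_hh_per_stratum = 1, cfg_hh_per_urban = 1,
                       cfg_pop_per_psu = 1, cfg_min_pop_per_cell = min_pop)
  build_frame(grid_from(popmat, cell), zones_from(stratmat, cell),
              if (!is.null(urbanmat)) zones_from(urbanmat, cell), cfg)
}

# seed set built directly (bypassing selection) for adjustment tests
seed_set_from <- function(frame, cell_ids, n_per_stratum = NULL, r = 0.5) {
  m <- match(cell_ids, frame$cell_id)
  stopifnot(!anyNA(m))
  seeds <- data.frame(cell_id = cell_ids,
                      stratum_id = frame$stratum_id[m],
                      urban = frame$urban[m])
  if (is.null(n_per_stratum)) {
    tab <- table(seeds$stratum_id)
    n_per_stratum <- stats::setNames(as.integer(tab), names(tab))
  }
  gridpsu:::new_seed_set(seeds, n_per_stratum, r)
}

# BFS 4-connectivity over (row, col) pairs
is_4_connected <- function(rows, cols) {
  n <- length(rows)
  if (n <= 1L) return(TRUE)
  key <- paste(rows, cols)
  seen <- logical(n); seen[1] <- TRUE
  queue <- 1L
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    nb <- paste(c(rows[i] - 1, rows[i] + 1, rows[i], rows[i]),
                c(cols[i], cols[i], cols[i] - 1, cols[i] + 1))
    hit <- which(!seen & key %in% nb)
    seen[hit] <- TRUE
    queue <- c(queue, hit)
  }
  all(seen)
}
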