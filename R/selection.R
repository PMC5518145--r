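#' Number of PSUs to select per stratum
#'
#' The per-stratum household target divided by the households sampled per
#' PSU, rounded up so the target is always met or exceeded. The urban
#' per-PSU value is used for allocation (it is the value used for all PSUs
#' when no rural value is given).
#'
#' @param cfg a [sample_config()].
#' @param strata_ids vector of stratum ids present in the frame.
#' @return named integer vector, one `n_k` per stratum.
#' @export
allocate_psus <- function(cfg, strata_ids) {
  n_k <- max(1L, as.integer(ceiling(cfg$cfg_hh_per_stratum / cfg$cfg_hh_per_urban)))
  stats::setNames(rep(n_k, length(strata_ids)), as.character(sort(unique(strata_ids))))
}

#' Systematic PPES selection along the serpentine order
#'
#' Classic systematic probability-proportionate-to-estimated-size sampling:
#' cells of one stratum are laid out on a population line in serpentine
#' order; with total population P and interval I = P / n_k, sampling points
#' u + k I (k = 0..n_k-1, u = start * I) each select the cell whose
#' half-open cumulative-population interval contains the point. A cell hit
#' more than once (population larger than I) keeps its first hit and later
#' hits advance to the next not-yet-selected cell in serpentine order,
#' wrapping within the stratum, so exactly `n_k` distinct cells return.
#'
#' @param frame a `grid_frame`.
#' @param stratum stratum id to sample within.
#' @param n_k number of seeds to select.
#' @param start random start in [0, 1).
#' @return integer vector of selected `cell_id`s, in selection order.
#' @export
systematic_ppes <- function(frame, stratum, n_k, start) {
  sub <- frame[frame$stratum_id == stratum, , drop = FALSE]
  if (nrow(sub) == 0L) stop("stratum ", stratum, " has no eligible cells")
  if (n_k > nrow(sub))
    stop("stratum ", stratum, ": n_k (", n_k, ") exceeds eligible cells (",
         nrow(sub), ")")
  if (start < 0 || start >= 1) stop("start must lie in [0, 1)")
  pop <- sub$population
  P <- sum(pop)
  if (P <= 0) stop("stratum ", stratum, " has zero population")
  I <- P / n_k
  pts <- (start + seq_len(n_k) - 1) * I
  edges <- c(0, cumsum(pop))
  idx <- findInterval(pts, edges, rightmost.closed = FALSE, all.inside = FALSE)
  idx[idx > nrow(sub)] <- nrow(sub)  # guard against pts == P from rounding
  taken <- logical(nrow(sub))
  out <- integer(n_k)
  for (k in seq_len(n_k)) {
    j <- idx[k]
    while (taken[j]) j <- if (j == nrow(sub)) 1L else j + 1L
    taken[j] <- TRUE
    out[k] <- sub$cell_id[j]
  }
  out
}

#' Select seed cells in every stratum
#'
#' Draws (or reuses) one master random number r in [0, 1) and applies
#' [systematic_ppes()] with start r independently in every stratum. The
#' same configuration, frame and r always reproduce the identical seed set;
#' the number used is recorded in the result so a sample can be reproduced
#' by passing it back as `cfg_random_number`.
#'
#' @param frame a `grid_frame`.
#' @param cfg a [sample_config()]; `cfg_random_number`, when set, is used as r.
#' @param rng optional `seeded_rng` used to draw r when `cfg_random_number`
#'   is absent; defaults to the session RNG.
#' @return a `seed_set`: list with `seeds` (data.frame `cell_id`,
#'   `stratum_id`, `urban`), `n_per_stratum`, and `random_number_used`.
#' @export
select_seeds <- function(frame, cfg, rng = NULL) {
  if (nrow(frame) == 0L) stop("empty frame")
  r <- cfg$cfg_random_number
  if (is.null(r)) r <- if (is.null(rng)) stats::runif(1) else rng$runif(1)
  strata_ids <- sort(unique(frame$stratum_id))
  n_per <- allocate_psus(cfg, strata_ids)
  cells <- unlist(lapply(strata_ids, function(s)
    systematic_ppes(frame, s, n_per[[as.character(s)]], r)), use.names = FALSE)
  m <- match(cells, frame$cell_id)
  seeds <- data.frame(cell_id = cells,
                      stratum_id = frame$stratum_id[m],
                      urban = frame$urban[m])
  new_seed_set(seeds, n_per, r)
}

new_seed_set <- function(seeds, n_per_stratum, random_number_used) {
  stopifnot(!anyDuplicated(seeds$cell_id))
  cnt <- table(factor(seeds$stratum_id, levels = names(n_per_stratum)))
  stopifnot(all(as.integer(cnt) == as.integer(n_per_stratum)))
  structure(list(seeds = seeds, n_per_stratum = n_per_stratum,
                 random_number_used = random_number_used),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set> %d seeds in %d strata (random number %.10f)\n",
              nrow(x$seeds), length(unique(x$seeds$stratum_id)),
              x$random_number_used))
  tab <- table(ifelse(x$seeds$urban, "urban", "rural"))
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
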