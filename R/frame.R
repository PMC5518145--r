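#' Build the serpentine-ordered sampling frame
#'
#' Combines the population grid, strata zones and (optional) urban mask into
#' one table of eligible cells — the sample frame. A cell is eligible when
#' its population is non-missing and at least `cfg_min_pop_per_cell` and it
#' has a stratum id. Cells are ranked in serpentine (boustrophedon) order:
#' rows taken north to south, scanned west-to-east on even grid rows and
#' east-to-west on odd rows, so consecutive frame cells are spatially
#' adjacent — the implicit spatial stratification that systematic sampling
#' exploits.
#'
#' @param pop a `pop_grid`.
#' @param strata a `zone_grid` of positive integer stratum ids.
#' @param urban optional binary `zone_grid` (1 urban / 0 rural); when absent
#'   every cell is rural. Cells with a missing urban value are kept as rural.
#' @param cfg a [sample_config()].
#' @return a `grid_frame`: a data.frame with columns `cell_id`, `row`, `col`
#'   (0-based), `x_center`, `y_center`, `population`, `stratum_id`, `urban`,
#'   `serpentine_index` (0-based), sorted by `serpentine_index`, carrying the
#'   grid geometry as attributes.
#' @export
build_frame <- function(pop, strata, urban = NULL, cfg) {
  if (!same_georeference(pop, strata))
    stop("strata grid does not match the population grid; rasterize inputs ",
         "onto the population grid first")
  if (!is.null(urban) && !same_georeference(pop, urban))
    stop("urban grid does not match the population grid; rasterize inputs ",
         "onto the population grid first")
  nr <- pop$n_rows; nc <- pop$n_cols
  row0 <- as.vector(row(pop$values)) - 1L
  col0 <- as.vector(col(pop$values)) - 1L
  p <- as.vector(pop$values)
  s <- as.vector(strata$values)
  u <- if (is.null(urban)) rep(FALSE, length(p))
       else !is.na(as.vector(urban$values)) & as.vector(urban$values) == 1
  eligible <- !is.na(p) & p >= cfg$cfg_min_pop_per_cell & !is.na(s)
  all_strata <- sort(unique(s[!is.na(s)]))
  empty <- setdiff(all_strata, unique(s[eligible]))
  if (length(empty))
    stop("stratum with zero eligible population: ", paste(empty, collapse = ", "))
  if (!any(eligible)) stop("no eligible cells in the frame")
  df <- data.frame(
    cell_id = which(eligible),
    row = row0[eligible], col = col0[eligible],
    x_center = pop$origin_x + (col0[eligible] + 0.5) * pop$cell_width,
    y_center = pop$origin_y - (row0[eligible] + 0.5) * pop$cell_height,
    population = p[eligible],
    stratum_id = as.integer(s[eligible]),
    urban = u[eligible]
  )
  serp_col <- ifelse(df$row %% 2L == 0L, df$col, nc - 1L - df$col)
  ord <- order(df$row, serp_col)
  df <- df[ord, , drop = FALSE]
  df$serpentine_index <- seq_len(nrow(df)) - 1L
  rownames(df) <- NULL
  structure(df,
            class = c("grid_frame", "data.frame"),
            n_rows = nr, n_cols = nc,
            origin_x = pop$origin_x, origin_y = pop$origin_y,
            cell_width = pop$cell_width, cell_height = pop$cell_height,
            crs_label = pop$crs_label)
}

frame_geometry <- function(frame) {
  list(n_rows = attr(frame, "n_rows"), n_cols = attr(frame, "n_cols"),
       origin_x = attr(frame, "origin_x"), origin_y = attr(frame, "origin_y"),
       cell_width = attr(frame, "cell_width"),
       cell_height = attr(frame, "cell_height"),
       crs_label = attr(frame, "crs_label"))
}

frame_cell_area_km2 <- function(frame) {
  g <- frame_geometry(frame)
  centroid_cell_size(structure(
    list(n_rows = g$n_rows, n_cols = g$n_cols, origin_x = g$origin_x,
         origin_y = g$origin_y, cell_width = g$cell_width,
         cell_height = g$cell_height, crs_label = g$crs_label),
    class = "pop_grid"))$area_km2
}
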