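#' Construct a population grid
#'
#' A `pop_grid` is the in-memory form of a gridded population raster: a
#' numeric matrix of estimated persons per cell plus the georeference needed
#' to place each cell on a map. Row 1 is the northernmost row, column 1 the
#' westernmost column; `origin_x`/`origin_y` are the coordinates of the
#' grid's west and north edges.
#'
#' @param values numeric matrix of persons per cell; `NA` marks missing data.
#' @param origin_x,origin_y map coordinates of the west edge and north edge.
#' @param cell_width,cell_height cell extents in map units (positive).
#' @param crs_label opaque coordinate-system label. Labels containing
#'   `"degree"` or `"4326"` are treated as geographic (degrees) when ground
#'   areas are needed; anything else is assumed to be metres.
#' @return An object of class `pop_grid`.
#' @export
pop_grid <- function(values, origin_x = 0, origin_y = nrow(values) * cell_height,
                     cell_width = 100, cell_height = cell_width,
                     crs_label = "local/metres") {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("grid must have at least one row and one column")
  if (cell_width <= 0 || cell_height <= 0)
    stop("cell_width and cell_height must be positive")
  if (any(!is.finite(values) & !is.na(values)))
    stop("non-finite cell values other than NA are not allowed")
  if (any(values < 0, na.rm = TRUE))
    stop("population values must be nonnegative")
  structure(
    list(values = values, n_rows = nrow(values), n_cols = ncol(values),
         origin_x = origin_x, origin_y = origin_y,
         cell_width = cell_width, cell_height = cell_height,
         crs_label = crs_label),
    class = "pop_grid"
  )
}

#' Construct a zone grid (integer zones on the same lattice)
#'
#' Zone grids carry stratum identifiers or a binary urban mask, aligned
#' cell-for-cell with a companion population grid.
#'
#' @inheritParams pop_grid
#' @param values integer matrix of zone ids (positive) or `NA`.
#' @return An object of class `zone_grid`.
#' @export
zone_grid <- function(values, origin_x = 0, origin_y = nrow(values) * cell_height,
                      cell_width = 100, cell_height = cell_width,
                      crs_label = "local/metres") {
  values <- as.matrix(values)
  if (any(values < 0, na.rm = TRUE))
    stop("zone ids must be nonnegative integers")
  if (any(values != round(values), na.rm = TRUE))
    stop("zone ids must be integers")
  g <- pop_grid(values, origin_x, origin_y, cell_width, cell_height, crs_label)
  class(g) <- "zone_grid"
  g
}

#' @export
print.pop_grid <- function(x, ...) {
  cat(sprintf("<%s> %d x %d cells, %.6g x %.6g map units/cell, origin (%.6g, %.6g), crs '%s'\n",
              class(x)[1], x$n_rows, x$n_cols, x$cell_width, x$cell_height,
              x$origin_x, x$origin_y, x$crs_label))
  cat(sprintf("  total (non-missing): %.6g; missing cells: %d\n",
              sum(x$values, na.rm = TRUE), sum(is.na(x$values))))
  invisible(x)
}

#' @export
print.zone_grid <- print.pop_grid

same_georeference <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$origin_x - b$origin_x) <= tol && abs(a$origin_y - b$origin_y) <= tol &&
    abs(a$cell_width - b$cell_width) <= tol &&
    abs(a$cell_height - b$cell_height) <= tol
}

crs_is_degrees <- function(crs_label) {
  grepl("degree|4326|wgs", tolower(crs_label %||% ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ground area of the grid's centroid cell, in km^2
#'
#' For geographic (degree) grids the representative cell is the one at the
#' grid's geographic centre, and its ground extent is computed from the
#' local metres-per-degree at that latitude; this single representative
#' size is used for all area computations (PSU area caps, coarse-grid
#' construction), which corrects for cells shrinking toward the poles.
#' Projected grids are assumed to be in metres.
#'
#' @param grid a `pop_grid` or `zone_grid`.
#' @return list with `side_x_m`, `side_y_m` (metres) and `area_km2`.
#' @export
centroid_cell_size <- function(grid) {
  if (crs_is_degrees(grid$crs_label)) {
    lat_centre <- grid$origin_y - grid$n_rows / 2 * grid$cell_height
    m_per_deg_lat <- 111320
    m_per_deg_lon <- 111320 * cos(lat_centre * pi / 180)
    sx <- grid$cell_width * m_per_deg_lon
    sy <- grid$cell_height * m_per_deg_lat
  } else {
    sx <- grid$cell_width
    sy <- grid$cell_height
  }
  list(side_x_m = sx, side_y_m = sy, area_km2 = sx * sy / 1e6)
}

# ---- ESRI ASCII grid I/O -------------------------------------------------

#' Read an ESRI ASCII grid raster
#'
#' The standard plain-text raster interchange format (`.asc`): a six-line
#' header (`ncols`, `nrows`, `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`,
#' `cellsize`, optional `NODATA_value`) followed by rows of values, north row
#' first. An optional sidecar file `<path>.crs` holding a single CRS label is
#' honoured.
#'
#' @param path path to the `.asc` file.
#' @param what `"pop"` for a population grid, `"zone"` for a zone grid.
#' @return a `pop_grid` or `zone_grid`.
#' @export
read_asc_grid <- function(path, what = c("pop", "zone")) {
  what <- match.arg(what)
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not a valid ESRI ASCII grid (missing header fields): ", path)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  xll <- hdr$xllcorner %||% (hdr$xllcenter - cs / 2)
  yll <- hdr$yllcorner %||% (hdr$yllcenter - cs / 2)
  if (is.null(xll) || is.null(yll)) stop("missing x/y lower-left corner in ", path)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               what = numeric(), quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, found %d in %s", nr * nc, length(vals), path))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  if (any(!is.finite(m) & !is.na(m)))
    stop("non-finite cell values other than the declared nodata in ", path)
  crs <- "unspecified/metres"
  crs_file <- paste0(path, ".crs")
  if (file.exists(crs_file)) crs <- trimws(readLines(crs_file, warn = FALSE)[1])
  ctor <- if (what == "pop") pop_grid else zone_grid
  ctor(m, origin_x = xll, origin_y = yll + nr * cs,
       cell_width = cs, cell_height = cs, crs_label = crs)
}

#' Write a grid as an ESRI ASCII grid raster
#'
#' Writes the `.asc` file plus a `<path>.crs` sidecar carrying the CRS label.
#' Cells must be square (the format has a single `cellsize`).
#'
#' @param grid a `pop_grid` or `zone_grid`.
#' @param path output path.
#' @param nodata value used to encode missing cells (default -9999).
#' @param digits significant digits for cell values; the default (17) makes
#'   a write/read round trip bit-exact for doubles.
#' @return `path`, invisibly.
#' @export
write_asc_grid <- function(grid, path, nodata = -9999, digits = 17) {
  if (abs(grid$cell_width - grid$cell_height) > 1e-12)
    stop("ESRI ASCII grids require square cells")
  m <- grid$values
  m[is.na(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10g", grid$origin_x),
    sprintf("yllcorner %.10g", grid$origin_y - grid$n_rows * grid$cell_height),
    sprintf("cellsize %.10g", grid$cell_width),
    sprintf("NODATA_value %.10g", nodata)
  )
  body <- apply(m, 1L, function(r) paste(formatC(r, digits = digits, format = "g"),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  writeLines(grid$crs_label, paste0(path, ".crs"))
  invisible(path)
}

#' Load a gridded population raster from disk
#'
#' @param path path to a single-band raster in ESRI ASCII grid format.
#' @return a `pop_grid` with missing-data cells flagged as `NA` and geometry
#'   taken from the file's georeference.
#' @export
load_population_raster <- function(path) read_asc_grid(path, "pop")

#' Load a zone raster (strata ids or urban mask) from disk
#'
#' @param path path to a raster in ESRI ASCII grid format.
#' @return a `zone_grid`.
#' @export
load_zone_raster <- function(path) read_asc_grid(path, "zone")

# ---- cell aggregation ----------------------------------------------------

#' Aggregate grid cells into coarser blocks
#'
#' Sums `factor` x `factor` blocks of cells into single coarser cells, e.g.
#' turning a 100 m grid into a 300 m sample frame with `factor = 3`. Missing
#' cells count as zero within a partially valid block; a block that is
#' missing everywhere stays missing. Partial blocks at the south/east edges
#' are retained.
#'
#' @param grid a `pop_grid`.
#' @param factor positive integer aggregation factor.
#' @return a `pop_grid` with cell extents scaled by `factor`.
#' @export
aggregate_cells <- function(grid, factor) {
  if (length(factor) != 1L || is.na(factor) || factor < 1 || factor != round(factor))
    stop("factor must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(grid)
  nr <- grid$n_rows; nc <- grid$n_cols
  nro <- ceiling(nr / factor); nco <- ceiling(nc / factor)
  ri <- (seq_len(nr) - 1L) %/% factor + 1L
  ci <- (seq_len(nc) - 1L) %/% factor + 1L
  v <- grid$values
  idx <- (ci[col(v)] - 1L) * nro + ri[row(v)]
  sums <- rep(0, nro * nco)
  valid <- rep(FALSE, nro * nco)
  ok <- !is.na(v)
  s <- tapply(v[ok], idx[ok], sum)
  sums[as.integer(names(s))] <- s
  valid[as.integer(names(s))] <- TRUE
  out <- matrix(sums, nrow = nro, ncol = nco)
  out[matrix(!valid, nrow = nro, ncol = nco)] <- NA
  pop_grid(out, origin_x = grid$origin_x, origin_y = grid$origin_y,
           cell_width = grid$cell_width * factor,
           cell_height = grid$cell_height * factor,
           crs_label = grid$crs_label)
}

# ---- urban classification ------------------------------------------------

#' Classify cells as urban by a population-density cut
#'
#' Finds the largest observed positive cell value `v` such that the cells
#' with value >= `v` (the most populous cells) hold at least
#' `urban_population_fraction` of the total population, and labels those
#' cells urban. This reproduces the construction "the density value at which
#' X% of the population lives in the most populous cells".
#'
#' @param grid a `pop_grid`.
#' @param urban_population_fraction fraction of total population to place in
#'   urban cells, in (0, 1].
#' @return list with `threshold` (persons per cell) and `urban` (a binary
#'   `zone_grid`: 1 urban, 0 rural, `NA` where population is missing).
#' @export
classify_urban_by_density <- function(grid, urban_population_fraction) {
  f <- urban_population_fraction
  if (length(f) != 1L || is.na(f) || f <= 0 || f > 1)
    stop("urban_population_fraction must be in (0, 1]")
  v <- grid$values
  total <- sum(v, na.rm = TRUE)
  if (total <= 0) stop("grid has no population; cannot classify urban cells")
  pos <- sort(unique(v[!is.na(v) & v > 0]), decreasing = TRUE)
  cum <- cumsum(vapply(pos, function(x) sum(v[!is.na(v) & v == x]), numeric(1)))
  threshold <- pos[match(TRUE, cum >= f * total)]
  u <- ifelse(is.na(v), NA_real_, as.numeric(v >= threshold))
  list(threshold = threshold,
       urban = zone_grid(matrix(u, nrow = grid$n_rows),
                         origin_x = grid$origin_x, origin_y = grid$origin_y,
                         cell_width = grid$cell_width,
                         cell_height = grid$cell_height,
                         crs_label = grid$crs_label))
}
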