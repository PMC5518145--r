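#' Per-stratum population totals
#'
#' Totals over eligible frame cells only: `str_pop` (all), `str_u_pop`
#' (urban), `str_r_pop` (rural) and `str_cells` (eligible cell count).
#'
#' @param frame a `grid_frame`.
#' @return data.frame with one row per stratum.
#' @export
summarize_strata <- function(frame) {
  if (nrow(frame) == 0L) stop("empty frame")
  sid <- sort(unique(frame$stratum_id))
  agg <- function(f) vapply(sid, function(s)
    sum(frame$population[frame$stratum_id == s & f(frame)]), numeric(1))
  data.frame(
    stratum_id = sid,
    str_pop = agg(function(fr) rep(TRUE, nrow(fr))),
    str_u_pop = agg(function(fr) fr$urban),
    str_r_pop = agg(function(fr) !fr$urban),
    str_cells = vapply(sid, function(s) sum(frame$stratum_id == s), numeric(1))
  )
}

#' Assemble the PSU attribute table
#'
#' One record per PSU with the standard output schema: `PSUid`, `stratum`,
#' `psu_pop`/`psu_r_pop`/`psu_u_pop`, `psus_in_stratum`,
#' `str_pop`/`str_r_pop`/`str_u_pop`, `str_cells`, `xCent`/`yCent` (seed-cell
#' centre; decimal degrees when the grid CRS is geographic, raw map units
#' otherwise — flagged in the output sidecar), and `U_R` ("U"/"R" from the
#' seed cell's classification).
#'
#' @param psus a `psu_set` from [grow_psus()].
#' @param strata_totals result of [summarize_strata()].
#' @return data.frame of PSU records, ordered by `PSUid`.
#' @export
psu_records <- function(psus, strata_totals) {
  p <- psus$psus
  m <- match(p$stratum_id, strata_totals$stratum_id)
  if (anyNA(m)) stop("PSU stratum missing from strata totals")
  n_in <- table(p$stratum_id)
  data.frame(
    PSUid = p$psu_id,
    stratum = p$stratum_id,
    psu_pop = p$psu_pop,
    psu_r_pop = p$psu_r_pop,
    psu_u_pop = p$psu_u_pop,
    psus_in_stratum = as.integer(n_in[as.character(p$stratum_id)]),
    str_pop = strata_totals$str_pop[m],
    str_r_pop = strata_totals$str_r_pop[m],
    str_u_pop = strata_totals$str_u_pop[m],
    str_cells = as.integer(strata_totals$str_cells[m]),
    xCent = p$centroid_x,
    yCent = p$centroid_y,
    U_R = ifelse(p$urban, "U", "R")
  )
}

# ---- dissolve member cells into boundary polygons --------------------------
# Union of axis-aligned cell squares via directed-edge cancellation: each
# member cell contributes its four boundary edges oriented counter-clockwise
# (interior on the left, in map coordinates with y up); an edge shared by two
# members appears once in each direction and cancels. The surviving edges are
# chained into rings, taking the leftmost turn at pinch vertices. Outer rings
# come out counter-clockwise (positive signed area), holes clockwise.

psu_polygon <- function(rows, cols, geom) {
  # lattice vertex key: (c, r) with c in 0..n_cols, r in 0..n_rows
  vkey <- function(c, r) c * (geom$n_rows + 1L) + r
  e_from <- integer(0); e_to <- integer(0)
  for (i in seq_along(rows)) {
    r <- rows[i]; c <- cols[i]
    nw <- vkey(c, r); ne <- vkey(c + 1L, r)
    sw <- vkey(c, r + 1L); se <- vkey(c + 1L, r + 1L)
    e_from <- c(e_from, sw, se, ne, nw)   # CCW in xy: S, E, N, W sides
    e_to   <- c(e_to,   se, ne, nw, sw)
  }
  key <- paste(e_from, e_to)
  rkey <- paste(e_to, e_from)
  cancel <- key %in% rkey
  e_from <- e_from[!cancel]; e_to <- e_to[!cancel]
  vx <- function(v) v %/% (geom$n_rows + 1L)   # lattice col
  vy <- function(v) v %% (geom$n_rows + 1L)    # lattice row
  used <- logical(length(e_from))
  rings <- list()
  turn_rank <- function(din, dout) {
    # din/dout: direction codes in xy; rank left > straight > right > back
    cross <- din[1] * dout[2] - din[2] * dout[1]
    dot <- din[1] * dout[1] + din[2] * dout[2]
    if (cross > 0) 3 else if (dot > 0) 2 else if (cross < 0) 1 else 0
  }
  edge_dir <- function(i) c(vx(e_to[i]) - vx(e_from[i]),
                            -(vy(e_to[i]) - vy(e_from[i])))
  while (any(!used)) {
    start <- which(!used)[1]
    path <- integer(0)
    cur <- start
    repeat {
      used[cur] <- TRUE
      path <- c(path, cur)
      nxt <- which(!used & e_from == e_to[cur])
      if (length(nxt) == 0L) break
      if (length(nxt) > 1L) {
        din <- edge_dir(cur)
        ranks <- vapply(nxt, function(j) turn_rank(din, edge_dir(j)), numeric(1))
        nxt <- nxt[which.max(ranks)]
      }
      cur <- nxt[1]
    }
    verts <- c(e_from[path], e_to[path[length(path)]])
    x <- geom$origin_x + vx(verts) * geom$cell_width
    y <- geom$origin_y - vy(verts) * geom$cell_height
    rings[[length(rings) + 1L]] <- cbind(x, y)
  }
  signed_area <- vapply(rings, function(rg) {
    x <- rg[, 1]; y <- rg[, 2]; n <- nrow(rg)
    sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
  }, numeric(1))
  rings[order(-signed_area)]   # exterior (largest positive area) first
}

#' Write the PSU layer (GeoJSON and/or CSV) plus a reproduction sidecar
#'
#' Writes one feature per PSU with the attribute schema of [psu_records()]
#' and a polygon geometry equal to the dissolved union of its member-cell
#' squares (holes from ineligible cells are preserved). A plain-text sidecar
#' `<base>_sidecar.txt` records the configuration, the coordinate units of
#' `xCent`/`yCent`, and the random number used, which reproduces the sample.
#'
#' @param psus a `psu_set`.
#' @param strata_totals result of [summarize_strata()].
#' @param frame the `grid_frame` the PSUs were grown on.
#' @param path output path without extension.
#' @param format any of `"geojson"`, `"csv"` (both by default). The ESRI
#'   shapefile dialect is not supported in this build (no binary GIS writer
#'   available); requesting it is an error.
#' @param cfg optional [sample_config()] echoed into the sidecar.
#' @param random_number_used the run's recorded random number.
#' @return named character vector of files written, invisibly.
#' @export
write_psu_layer <- function(psus, strata_totals, frame, path,
                            format = c("geojson", "csv"), cfg = NULL,
                            random_number_used = NULL) {
  format <- match.arg(format, c("geojson", "csv", "shapefile"), several.ok = TRUE)
  if ("shapefile" %in% format)
    stop("shapefile output is not supported in this build; use geojson ",
         "(full field names, no 10-character truncation) or csv")
  rec <- psu_records(psus, strata_totals)
  geom <- frame_geometry(frame)
  files <- character(0)
  if ("csv" %in% format) {
    f <- paste0(path, ".csv")
    utils::write.csv(rec, f, row.names = FALSE)
    files["csv"] <- f
  }
  if ("geojson" %in% format) {
    feats <- lapply(seq_len(nrow(rec)), function(i) {
      mm <- match(psus$members[[rec$PSUid[i]]], frame$cell_id)
      rings <- psu_polygon(frame$row[mm], frame$col[mm], geom)
      coords <- lapply(rings, function(rg)
        lapply(seq_len(nrow(rg)), function(j) c(rg[j, 1], rg[j, 2])))
      list(type = "Feature",
           properties = as.list(rec[i, , drop = FALSE]),
           geometry = list(type = "Polygon", coordinates = coords))
    })
    fc <- list(type = "FeatureCollection",
               crs_label = geom$crs_label,
               features = feats)
    f <- paste0(path, ".geojson")
    writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA,
                                null = "null"), f)
    files["geojson"] <- f
  }
  sidecar <- paste0(path, "_sidecar.txt")
  lines <- c(
    "# sampling run sidecar",
    sprintf("random_number_used = %.15f",
            random_number_used %||% NA_real_),
    sprintf("centroid_units = %s",
            if (crs_is_degrees(geom$crs_label)) "decimal degrees"
            else "map units (projected CRS; not decimal degrees)"),
    sprintf("crs_label = %s", geom$crs_label))
  if (!is.null(cfg))
    lines <- c(lines, vapply(setdiff(names(cfg), "cfg_random_number"),
                             function(k) sprintf("%s = %s", k,
                                                 format(cfg[[k]] %||% "")),
                             character(1)))
  writeLines(lines, sidecar)
  files["sidecar"] <- sidecar
  invisible(files)
}
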