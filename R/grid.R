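#' Expand and snap a geographic bounding box
#'
#' Expands a lon/lat bounding box outwards by a metric buffer and snaps the
#' limits to a tenth-of-a-degree graticule. The buffer is converted to
#' degrees on the sphere (longitude at the mid-latitude of the box); each
#' limit is then snapped down to the nearest multiple of `round_deg`
#' (snapping down on every side reproduces the conventional printed limits
#' for study regions defined this way).
#'
#' @param bbox Numeric vector `c(lon_min, lon_max, lat_min, lat_max)` in
#'   decimal degrees (western longitudes negative).
#' @param buffer_km Outward buffer in kilometres applied to each side.
#' @param round_deg Snap increment in degrees; `0` disables snapping.
#' @return Expanded bbox in the same `c(lon_min, lon_max, lat_min, lat_max)`
#'   layout.
#' @examples
#' expand_bbox(c(-99.9, -97.8, 18.6, 20.2))  # -100.4 -97.4 18.1 20.6
#' @export
expand_bbox <- function(bbox, buffer_km = 50, round_deg = 0.1) {
  stopifnot(length(bbox) == 4)
  if (bbox[1] >= bbox[2] || bbox[3] >= bbox[4]) {
    stop("inverted bounding box: require lon_min < lon_max and lat_min < lat_max")
  }
  km_per_deg <- pi * .SPHERE_RADIUS_M / 180 / 1000
  blat <- buffer_km / km_per_deg
  mid_lat <- (bbox[3] + bbox[4]) / 2
  blon <- buffer_km / (km_per_deg * cos(mid_lat * pi / 180))
  out <- c(bbox[1] - blon, bbox[2] + blon, bbox[3] - blat, bbox[4] + blat)
  if (round_deg > 0) {
    out <- floor(out / round_deg + 1e-9) * round_deg
  }
  out
}

#' Build the 1 km sinusoidal master grid for a study region
#'
#' Lays a regular lattice of `cell_m`-sized cells in the sinusoidal
#' projection over the (buffered, snapped) bounding box and keeps the cells
#' whose centroid falls inside the box. Row 1 is the southernmost row.
#'
#' @param region_bbox_deg Bounding box `c(lon_min, lon_max, lat_min, lat_max)`
#'   of the prediction region, degrees.
#' @param buffer_km Buffer applied by [expand_bbox()].
#' @param round_deg Snap increment for [expand_bbox()].
#' @param cell_m Cell size in metres (default: the standard 1 km LST grid
#'   cell, 926.625433 m).
#' @param prediction_bbox_deg Optional inner bbox marking the prediction
#'   area; defaults to `region_bbox_deg` (cells inside it get
#'   `in_prediction_area = TRUE`).
#' @return A `master_grid` object: list with `cells` (data.frame of
#'   `cell_id, row, col, x, y, lon, lat, elev_m, in_prediction_area`),
#'   lattice metadata (`nrow, ncol, cell_m, x0, y0`), the expanded `bbox`,
#'   and an `ndvi` matrix slot (filled by [monthly_ndvi()] or the synthetic
#'   generator).
#' @export
build_master_grid <- function(region_bbox_deg, buffer_km = 50, round_deg = 0.1,
                              cell_m = .CELL_M,
                              prediction_bbox_deg = region_bbox_deg) {
  bbox <- expand_bbox(region_bbox_deg, buffer_km, round_deg)
  n_rows <- round((bbox[4] - bbox[3]) * pi / 180 * .SPHERE_RADIUS_M / cell_m)
  y0 <- .SPHERE_RADIUS_M * bbox[3] * pi / 180
  # x extent taken at the latitude of maximal width (closest to the equator)
  lat_ref <- if (bbox[3] >= 0) bbox[3] else if (bbox[4] <= 0) bbox[4] else 0
  cref <- cos(lat_ref * pi / 180)
  x0 <- .SPHERE_RADIUS_M * bbox[1] * pi / 180 * cref
  x1 <- .SPHERE_RADIUS_M * bbox[2] * pi / 180 * cref
  n_cols <- max(1L, ceiling((x1 - x0) / cell_m))

  rc <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  x <- x0 + (rc$col - 0.5) * cell_m
  y <- y0 + (rc$row - 0.5) * cell_m
  ll <- sinusoidal_to_lonlat(x, y)
  keep <- ll[, "lon"] >= bbox[1] & ll[, "lon"] <= bbox[2] &
    ll[, "lat"] >= bbox[3] & ll[, "lat"] <= bbox[4]
  cells <- data.frame(
    cell_id = (rc$row - 1L) * n_cols + rc$col,
    row = rc$row, col = rc$col, x = x, y = y,
    lon = ll[, "lon"], lat = ll[, "lat"], elev_m = NA_real_
  )[keep, , drop = FALSE]
  rownames(cells) <- NULL
  pb <- prediction_bbox_deg
  cells$in_prediction_area <- cells$lon >= pb[1] & cells$lon <= pb[2] &
    cells$lat >= pb[3] & cells$lat <= pb[4]

  structure(list(cells = cells, ndvi = NULL,
                 nrow = n_rows, ncol = n_cols, cell_m = cell_m,
                 x0 = x0, y0 = y0, bbox = bbox),
            class = "master_grid")
}

#' @export
print.master_grid <- function(x, ...) {
  cat(sprintf("master_grid: %d x %d lattice (%.3f m cells), %d retained cells\n",
              x$nrow, x$ncol, x$cell_m, nrow(x$cells)))
  cat(sprintf("  bbox: %.2f to %.2f lon, %.2f to %.2f lat\n",
              x$bbox[1], x$bbox[2], x$bbox[3], x$bbox[4]))
  cat(sprintf("  prediction-area cells: %d; NDVI: %s; elevation: %s\n",
              sum(x$cells$in_prediction_area),
              if (is.null(x$ndvi)) "absent" else "12 months",
              if (all(is.na(x$cells$elev_m))) "absent" else "present"))
  invisible(x)
}

#' Aggregate a fine-resolution DEM to grid-cell elevations
#'
#' Applies a Gaussian filter (default 150 m SD) to the fine elevation raster
#' and extracts the smoothed values at the master-grid cell centroids
#' (nearest fine cell).
#'
#' @param dem_fine List describing the fine raster in sinusoidal
#'   coordinates: `x0`, `y0` (lower-left corner, m), `res_m` (cell size, m)
#'   and `z` (matrix, rows = south-to-north, cols = west-to-east).
#' @param grid A `master_grid`.
#' @param sigma_m Gaussian filter SD in metres.
#' @return The grid with `cells$elev_m` filled; centroids outside DEM
#'   coverage are left `NA`.
#' @export
aggregate_elevation <- function(dem_fine, grid, sigma_m = 150) {
  stopifnot(is.matrix(dem_fine$z), dem_fine$res_m > 0)
  z <- gauss_smooth(dem_fine$z, sigma_m / dem_fine$res_m)
  ri <- ceiling((grid$cells$y - dem_fine$y0) / dem_fine$res_m - 0.5 + 1e-9) + 0L
  ci <- ceiling((grid$cells$x - dem_fine$x0) / dem_fine$res_m - 0.5 + 1e-9) + 0L
  ri <- pmax(1L, ri); ci <- pmax(1L, ci)  # centroid exactly on the edge
  ok <- ri >= 1L & ri <= nrow(z) & ci >= 1L & ci <= ncol(z) &
    grid$cells$y >= dem_fine$y0 & grid$cells$x >= dem_fine$x0 &
    grid$cells$y <= dem_fine$y0 + nrow(z) * dem_fine$res_m &
    grid$cells$x <= dem_fine$x0 + ncol(z) * dem_fine$res_m
  ev <- rep(NA_real_, nrow(grid$cells))
  ev[ok] <- z[cbind(ri[ok], ci[ok])]
  grid$cells$elev_m <- ev
  grid
}

#' Average two satellites' monthly NDVI
#'
#' Per month, the mean of the two sources; where one is missing the other is
#' used; both missing stays missing.
#'
#' @param sat1_monthly,sat2_monthly Numeric matrices, cells x 12 months.
#'   Either may be `NULL` (single-source fallback).
#' @return Cells x 12 matrix of combined NDVI.
#' @export
monthly_ndvi <- function(sat1_monthly, sat2_monthly) {
  a <- sat1_monthly; b <- sat2_monthly
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  stopifnot(identical(dim(a), dim(b)))
  if (ncol(a) != 12) stop("NDVI matrices must have 12 monthly columns")
  out <- (ifelse(is.na(a), 0, a) + ifelse(is.na(b), 0, b)) /
    ((!is.na(a)) + (!is.na(b)))
  out[is.na(a) & is.na(b)] <- NA_real_
  out
}

#' Assign stations to master-grid cells
#'
#' Maps each station to the cell containing it; a station exactly on a
#' shared cell edge goes to the lower cell index (deterministic tie rule).
#'
#' @param stations data.frame with `station_id`, `lon`, `lat`.
#' @param grid A `master_grid`.
#' @return `stations` with a `cell_id` column added.
#' @export
assign_station_cells <- function(stations, grid) {
  xy <- lonlat_to_sinusoidal(stations$lon, stations$lat)
  # cell c spans continuous index (c-1, c]; ceiling() sends a point exactly
  # on a shared edge to the lower cell index (deterministic tie rule)
  ri <- ceiling((xy[, "y"] - grid$y0) / grid$cell_m - 1e-9)
  ci <- ceiling((xy[, "x"] - grid$x0) / grid$cell_m - 1e-9)
  ri <- pmax(1L, pmin(grid$nrow, as.integer(ri)))
  ci <- pmax(1L, pmin(grid$ncol, as.integer(ci)))
  cell_id <- (ri - 1L) * grid$ncol + ci
  bad <- stations$lon < grid$bbox[1] | stations$lon > grid$bbox[2] |
    stations$lat < grid$bbox[3] | stations$lat > grid$bbox[4] |
    !(cell_id %in% grid$cells$cell_id)
  if (any(bad)) {
    stop("station(s) outside the study area: ",
         paste(stations$station_id[bad], collapse = ", "))
  }
  stations$cell_id <- as.integer(cell_id)
  stations
}
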