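# Extreme-temperature exposure: percentile maps, person-day counts, and
# population allocation from census polygons to grid cells.

#' Per-cell percentile of a daily prediction stack
#'
#' @param prediction_stack Matrix cells x days (`NA` days excluded).
#' @param q Percentile in (0, 100]; `q = 100` gives the per-cell maximum.
#' @return Numeric vector per cell; cells with zero predicted days are
#'   `NA`.
#' @export
percentile_surface <- function(prediction_stack, q = 95) {
  apply(prediction_stack, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_real_)
    stats::quantile(v, q / 100, type = 7, names = FALSE)
  })
}

#' Person-days of exposure to extreme cold and heat
#'
#' Counts, per cell, days with predicted minimum temperature at or below
#' the cold threshold and days with predicted maximum at or above the hot
#' threshold (inclusive thresholds), and multiplies by the cell's
#' population aged 65+.
#'
#' @param prediction_stack_min,prediction_stack_max Matrices cells x days.
#' @param population Numeric vector: population aged >= 65 per cell.
#' @param cold_c,hot_c Thresholds in degC (defaults 5 and 30).
#' @return An `exposure_surface`: data.frame per cell (`population_65plus`,
#'   `days_cold`, `days_hot`, `person_days_cold`, `person_days_hot`) with
#'   region totals in the `totals` attribute.
#' @export
person_days <- function(prediction_stack_min, prediction_stack_max,
                        population, cold_c = 5, hot_c = 30) {
  if (!identical(dim(prediction_stack_min), dim(prediction_stack_max)) ||
      nrow(prediction_stack_min) != length(population)) {
    stop("prediction stacks and population grid are misaligned")
  }
  days_cold <- rowSums(prediction_stack_min <= cold_c, na.rm = TRUE)
  days_hot <- rowSums(prediction_stack_max >= hot_c, na.rm = TRUE)
  out <- data.frame(
    population_65plus = population,
    days_cold = days_cold, days_hot = days_hot,
    person_days_cold = population * days_cold,
    person_days_hot = population * days_hot)
  attr(out, "totals") <- c(person_days_cold = sum(out$person_days_cold),
                           person_days_hot = sum(out$person_days_hot))
  class(out) <- c("exposure_surface", "data.frame")
  out
}

#' @export
print.exposure_surface <- function(x, ...) {
  tot <- attr(x, "totals")
  cat(sprintf("exposure_surface: %d cells, population %.0f\n",
              nrow(x), sum(x$population_65plus)))
  cat(sprintf("  person-days cold: %.0f; person-days hot: %.0f\n",
              tot["person_days_cold"], tot["person_days_hot"]))
  invisible(x)
}

# Sutherland-Hodgman clip of a polygon (two-column matrix, closed
# implicitly) against an axis-aligned rectangle; returns the clipped
# polygon matrix (possibly 0 rows).
clip_polygon_rect <- function(poly, xmin, xmax, ymin, ymax) {
  clip_edge <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0) return(pts)
    out <- matrix(numeric(0), 0, 2)
    for (i in seq_len(n)) {
      cur <- pts[i, ]; prev <- pts[if (i == 1) n else i - 1, ]
      ci <- inside(cur); pi <- inside(prev)
      if (ci) {
        if (!pi) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (pi) {
        out <- rbind(out, intersect(prev, cur))
      }
    }
    out
  }
  ix <- function(p, q, at, coord) {
    t <- (at - p[coord]) / (q[coord] - p[coord])
    p + t * (q - p)
  }
  poly <- clip_edge(poly, function(p) p[1] >= xmin, function(p, q) ix(p, q, xmin, 1))
  poly <- clip_edge(poly, function(p) p[1] <= xmax, function(p, q) ix(p, q, xmax, 1))
  poly <- clip_edge(poly, function(p) p[2] >= ymin, function(p, q) ix(p, q, ymin, 2))
  poly <- clip_edge(poly, function(p) p[2] <= ymax, function(p, q) ix(p, q, ymax, 2))
  poly
}

# shoelace area of a polygon matrix
polygon_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Allocate polygon population counts to grid cells
#'
#' Each polygon's population is distributed over the grid cells it
#' intersects, proportionally to intersection area (areal weighting), in
#' the grid's projected coordinates. Total population is conserved for
#' polygons inside the grid.
#'
#' @param polygons List of two-column matrices (x, y in the grid's
#'   sinusoidal metres; or lon/lat with `lonlat = TRUE`), one per polygon.
#' @param population Numeric vector of polygon population counts.
#' @param grid A `master_grid`.
#' @param lonlat Are polygon vertices lon/lat degrees (projected first)?
#' @return Numeric vector: population per retained grid cell.
#' @export
polygons_to_grid <- function(polygons, population, grid, lonlat = FALSE) {
  stopifnot(length(polygons) == length(population))
  cells <- grid$cells
  out <- numeric(nrow(cells))
  h <- grid$cell_m / 2
  for (pi in seq_along(polygons)) {
    poly <- as.matrix(polygons[[pi]])
    if (nrow(poly) < 3 || anyNA(poly)) {
      stop("invalid polygon geometry at index ", pi)
    }
    if (lonlat) poly <- lonlat_to_sinusoidal(poly[, 1], poly[, 2])
    # candidate cells: bounding-box overlap
    bx <- range(poly[, 1]); by <- range(poly[, 2])
    cand <- which(cells$x + h >= bx[1] & cells$x - h <= bx[2] &
                    cells$y + h >= by[1] & cells$y - h <= by[2])
    if (length(cand) == 0) next
    areas <- vapply(cand, function(ci) {
      polygon_area(clip_polygon_rect(poly,
                                     cells$x[ci] - h, cells$x[ci] + h,
                                     cells$y[ci] - h, cells$y[ci] + h))
    }, numeric(1))
    tot <- sum(areas)
    if (tot > 0) out[cand] <- out[cand] + population[pi] * areas / tot
  }
  out
}

#' Read population polygons from a GeoJSON file
#'
#' Parses a GeoJSON FeatureCollection of Polygon features (outer rings
#' only) carrying a population property.
#'
#' @param path GeoJSON file path.
#' @param population_field Property name holding the population count.
#' @return List with `polygons` (list of lon/lat matrices) and
#'   `population` (numeric vector).
#' @export
read_population_geojson <- function(path, population_field = "pop65") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features
  polys <- list(); pop <- numeric(0)
  for (f in feats) {
    if (!identical(f$geometry$type, "Polygon")) next
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    # drop the closing vertex if repeated
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    polys[[length(polys) + 1]] <- m
    pop <- c(pop, as.numeric(f$properties[[population_field]]))
  }
  list(polygons = polys, population = pop)
}
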