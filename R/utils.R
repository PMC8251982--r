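# Internal helpers shared across modules.

# Earth radius (m) and cell height (m) of the standard 1 km sinusoidal grid.
.SPHERE_RADIUS_M <- 6371007.181
.CELL_M <- 926.625433

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded generators do not
#' perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a bounded child seed from a parent seed and a stage label, so one
# pipeline seed fans out deterministically without seed collisions.
child_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Gaussian smoothing of a matrix (separable kernel, renormalised at edges)
#'
#' Kernel truncated at 3 SD; edge renormalisation keeps constant fields
#' exactly constant. `sigma` is in units of matrix cells.
#' @noRd
gauss_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  half <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  smooth_1d <- function(m) {
    # convolve each column with k, renormalising by the in-bounds kernel mass
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    wsum <- numeric(n)
    for (o in seq(-half, half)) {
      w <- k[o + half + 1L]
      src <- pmin(pmax(seq_len(n) + o, 1L), n)
      inb <- (seq_len(n) + o >= 1L) & (seq_len(n) + o <= n)
      out[inb, ] <- out[inb, ] + w * m[src[inb], , drop = FALSE]
      wsum[inb] <- wsum[inb] + w
    }
    out / wsum
  }
  t(smooth_1d(t(smooth_1d(mat))))
}

# Spatially correlated Gaussian field: smoothed white noise rescaled to unit
# sample SD (so callers control the marginal SD directly).
correlated_field <- function(rows, cols, range_cells) {
  z <- matrix(rnorm(rows * cols), rows, cols)
  s <- gauss_smooth(z, range_cells)
  sd_s <- stats::sd(as.vector(s))
  if (sd_s == 0) return(s * 0)
  (s - mean(s)) / sd_s
}

#' Sinusoidal map projection (sphere)
#'
#' Forward and inverse mapping between geographic coordinates (degrees) and
#' the sinusoidal projection used by the 1 km LST grid products.
#'
#' @param lon,lat Longitude/latitude in decimal degrees.
#' @param x,y Projected coordinates in metres.
#' @param radius Sphere radius in metres.
#' @return A two-column matrix (`x`,`y`) or (`lon`,`lat`).
#' @export
lonlat_to_sinusoidal <- function(lon, lat, radius = .SPHERE_RADIUS_M) {
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  cbind(x = radius * lam * cos(phi), y = radius * phi)
}

#' @rdname lonlat_to_sinusoidal
#' @export
sinusoidal_to_lonlat <- function(x, y, radius = .SPHERE_RADIUS_M) {
  phi <- y / radius
  lam <- ifelse(cos(phi) == 0, 0, x / (radius * cos(phi)))
  cbind(lon = lam * 180 / pi, lat = phi * 180 / pi)
}

# Great-circle distance in km between two sets of points (degrees).
dist_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = .SPHERE_RADIUS_M) / 1000
}

# Pairwise great-circle distance matrix (km) for a station table.
dist_matrix_km <- function(lon, lat) {
  geosphere::distm(cbind(lon, lat),
                   fun = function(a, b) geosphere::distHaversine(a, b, r = .SPHERE_RADIUS_M)) / 1000
}

# days in a calendar year
days_in_year <- function(year) {
  if ((year %% 4 == 0 && year %% 100 != 0) || year %% 400 == 0) 366L else 365L
}

# season label from calendar month: Nov-Feb cold_dry, Mar-Apr warm_dry,
# May-Oct rainy
season_of_month <- function(month) {
  s <- ifelse(month %in% c(11, 12, 1, 2), "cold_dry",
              ifelse(month %in% c(3, 4), "warm_dry", "rainy"))
  factor(s, levels = c("cold_dry", "warm_dry", "rainy"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
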