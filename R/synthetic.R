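#' Simulate a synthetic study region
#'
#' Builds a `master_grid`-compatible region on the 1 km sinusoidal lattice
#' with a smooth (spatially correlated) elevation field and 12 monthly NDVI
#' grids carrying a seasonal cycle. The defaults emulate a central-plateau
#' region with plains, hills, and mountains: elevations spanning warm
#' lowland valleys (~1,400 m) to cold highlands (~4,500 m), so annual mean
#' temperatures range from roughly 4 to 26 degC under the default lapse
#' rate, and vegetation peaks in the rainy season.
#'
#' @param rows,cols Lattice dimensions (>= 8).
#' @param seed Integer seed; identical seeds give identical regions.
#' @param base_lon,base_lat Lon/lat (degrees) of the region's south-west
#'   corner.
#' @param elev_range Elevation range in metres the smooth field is scaled to.
#' @param elev_corr_cells Correlation length (cells) of the elevation field.
#' @param ndvi_base,ndvi_amp Mean level and seasonal amplitude of NDVI.
#' @param ndvi_corr_cells Correlation length (cells) of the NDVI spatial
#'   component.
#' @param prediction_fraction Fraction of the lattice (centred) marked as the
#'   prediction area.
#' @param cell_m Cell size in metres.
#' @return A `master_grid` with `elev_m` filled and a cells x 12 `ndvi`
#'   matrix.
#' @export
simulate_region <- function(rows, cols, seed = NULL,
                            base_lon = -99.5, base_lat = 19.0,
                            elev_range = c(1400, 4500),
                            elev_corr_cells = 6,
                            ndvi_base = 0.35, ndvi_amp = 0.25,
                            ndvi_corr_cells = 4,
                            prediction_fraction = 0.7,
                            cell_m = .CELL_M) {
  if (rows < 8 || cols < 8) stop("rows and cols must both be >= 8")
  with_seed(seed, {
    y0 <- .SPHERE_RADIUS_M * base_lat * pi / 180
    x0 <- .SPHERE_RADIUS_M * base_lon * pi / 180 * cos(base_lat * pi / 180)
    rc <- expand.grid(col = seq_len(cols), row = seq_len(rows))
    x <- x0 + (rc$col - 0.5) * cell_m
    y <- y0 + (rc$row - 0.5) * cell_m
    ll <- sinusoidal_to_lonlat(x, y)

    ef <- correlated_field(rows, cols, elev_corr_cells)
    ef <- (ef - min(ef)) / (max(ef) - min(ef))
    elev <- elev_range[1] + ef * diff(elev_range)

    ndvi_sp <- correlated_field(rows, cols, ndvi_corr_cells) * 0.12
    ndvi <- sapply(1:12, function(m) {
      ndvi_base + ndvi_amp * cos(2 * pi * (m - 8) / 12) +
        ndvi_sp[cbind(rc$row, rc$col)]
    })
    ndvi[] <- pmin(1, pmax(-1, ndvi))

    rmid <- (rows + 1) / 2; cmid <- (cols + 1) / 2
    in_pred <- abs(rc$row - rmid) <= prediction_fraction * rows / 2 &
      abs(rc$col - cmid) <= prediction_fraction * cols / 2

    cells <- data.frame(
      cell_id = (rc$row - 1L) * cols + rc$col,
      row = rc$row, col = rc$col, x = x, y = y,
      lon = ll[, "lon"], lat = ll[, "lat"],
      elev_m = elev[cbind(rc$row, rc$col)],
      in_prediction_area = in_pred
    )
    dlat <- cell_m / .SPHERE_RADIUS_M * 180 / pi
    bbox <- c(min(cells$lon) - dlat, max(cells$lon) + dlat,
              base_lat, base_lat + rows * dlat)
    structure(list(cells = cells, ndvi = ndvi,
                   nrow = rows, ncol = cols, cell_m = cell_m,
                   x0 = x0, y0 = y0, bbox = bbox),
              class = "master_grid")
  })
}

# default generative parameters for simulate_truth
truth_params <- function(intercept = 30, lapse = -0.0065,
                         sin_coef = -0.5, cos_coef = -3,
                         ndvi_coef = -1,
                         day_intercept_sd = 2,
                         residual_sd = 0.8, residual_corr_cells = 5,
                         gap_min = 5.5, gap_max = 5.5, gap_log_sd = 0.15) {
  list(intercept = intercept, lapse = lapse, sin_coef = sin_coef,
       cos_coef = cos_coef, ndvi_coef = ndvi_coef,
       day_intercept_sd = day_intercept_sd, residual_sd = residual_sd,
       residual_corr_cells = residual_corr_cells,
       gap_min = gap_min, gap_max = gap_max, gap_log_sd = gap_log_sd)
}

#' Simulate true daily air-temperature fields
#'
#' Generates daily minimum, mean, and maximum near-surface air temperature
#' for every grid cell of a synthetic region: a deterministic linear
#' predictor (elevation lapse, seasonal sine/cosine, NDVI), a day-level
#' random intercept (synoptic weather), and a spatially correlated residual
#' field. Minimum and maximum are the mean offset by strictly positive
#' lognormal half-ranges, so `tmin < tmean < tmax` holds by construction.
#'
#' @param region A `master_grid` from [simulate_region()].
#' @param year Calendar year (365- or 366-day).
#' @param params Generative parameters, see `truth_params()` via `...`
#'   overrides.
#' @param seed Integer seed.
#' @param ... Overrides for individual generative parameters
#'   (e.g. `residual_sd = 0`).
#' @return A `ta_truth` object: `ta` array (cells x days x
#'   `c("tmin","tmean","tmax")`), `dates`, `grid`, `params`
#'   (including the realised per-day intercepts), `seed`.
#' @export
simulate_truth <- function(region, year = 2018, params = NULL, seed = NULL, ...) {
  p <- params %||% truth_params()
  dots <- list(...)
  p[names(dots)] <- dots
  nd <- days_in_year(year)
  dates <- seq(as.Date(sprintf("%d-01-01", year)), by = "day", length.out = nd)
  cells <- region$cells
  n <- nrow(cells)
  tt <- (seq_len(nd) - 1) / (nd - 1)
  month <- as.integer(format(dates, "%m"))

  with_seed(seed, {
    u <- rnorm(nd, 0, p$day_intercept_sd)
    ta <- array(NA_real_, c(n, nd, 3),
                dimnames = list(NULL, NULL, c("tmin", "tmean", "tmax")))
    fixed_cell <- p$intercept + p$lapse * cells$elev_m
    for (j in seq_len(nd)) {
      e <- if (p$residual_sd > 0) {
        f <- correlated_field(region$nrow, region$ncol, p$residual_corr_cells)
        p$residual_sd * f[cbind(cells$row, cells$col)]
      } else 0
      tmean <- fixed_cell + p$sin_coef * sin(2 * pi * tt[j]) +
        p$cos_coef * cos(2 * pi * tt[j]) +
        p$ndvi_coef * region$ndvi[, month[j]] + u[j] + e
      g1 <- p$gap_min * exp(if (p$gap_log_sd > 0) rnorm(n, 0, p$gap_log_sd) else 0)
      g2 <- p$gap_max * exp(if (p$gap_log_sd > 0) rnorm(n, 0, p$gap_log_sd) else 0)
      ta[, j, "tmean"] <- tmean
      ta[, j, "tmin"] <- tmean - g1
      ta[, j, "tmax"] <- tmean + g2
    }
    p$day_intercepts <- u
    structure(list(ta = ta, dates = dates, year = year, grid = region,
                   params = p, seed = seed),
              class = "ta_truth")
  })
}

#' @export
print.ta_truth <- function(x, ...) {
  cat(sprintf("ta_truth: %d cells x %d days (%d), outcomes tmin/tmean/tmax\n",
              dim(x$ta)[1], dim(x$ta)[2], x$year))
  cat(sprintf("  tmean range %.1f to %.1f degC\n",
              min(x$ta[, , "tmean"]), max(x$ta[, , "tmean"])))
  invisible(x)
}

#' Simulate one satellite's daily LST stack
#'
#' Day and night LST are affine, day-varying-slope functions of the true air
#' temperature plus noise: `LST = a_j + b_j * Ta + eps`, with the slope
#' `b_j` drawn per day. Cloud-driven missingness is planted as spatially
#' correlated blobs hitting close to `missing_fraction` of cells each day.
#'
#' @param truth A `ta_truth`.
#' @param slopes_by_day Optional list with numeric vectors `a_day`, `b_day`,
#'   `a_night`, `b_night` (length = days); drawn randomly when omitted
#'   (`b ~ N(0.6, 0.15)`).
#' @param noise_sd Measurement noise SD in degC (default 2).
#' @param missing_fraction Target per-day missing-cell fraction, in
#'   `[0, 0.9]`.
#' @param seed Integer seed.
#' @param basis Which truth outcome drives each variable
#'   (default day <- tmax, night <- tmin).
#' @param missing_corr_cells Correlation length of the cloud blobs.
#' @return An `lst_stack`: matrices `day`, `night` (cells x days, `NA` =
#'   missing), `imputed_day`/`imputed_night` indicator matrices (all zero
#'   here), `dates`, `year`, and the realised `slopes_by_day`.
#' @export
simulate_lst <- function(truth, slopes_by_day = NULL, noise_sd = 2,
                         missing_fraction = 0.3, seed = NULL,
                         basis = c(day = "tmax", night = "tmin"),
                         missing_corr_cells = 4) {
  if (missing_fraction < 0 || missing_fraction > 0.9) {
    stop("missing_fraction must be in [0, 0.9]")
  }
  nd <- length(truth$dates)
  n <- dim(truth$ta)[1]
  region <- truth$grid
  with_seed(seed, {
    s <- slopes_by_day %||% list(
      a_day = rnorm(nd, 15, 1), b_day = rnorm(nd, 0.6, 0.15),
      a_night = rnorm(nd, -2, 1), b_night = rnorm(nd, 0.6, 0.15)
    )
    for (f in c("a_day", "b_day", "a_night", "b_night")) {
      if (length(s[[f]]) == 1) s[[f]] <- rep(s[[f]], nd)
    }
    day <- night <- matrix(NA_real_, n, nd)
    for (j in seq_len(nd)) {
      dn <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
      nn <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
      day[, j] <- s$a_day[j] + s$b_day[j] * truth$ta[, j, basis[["day"]]] + dn
      night[, j] <- s$a_night[j] + s$b_night[j] * truth$ta[, j, basis[["night"]]] + nn
      if (missing_fraction > 0) {
        for (v in c("day", "night")) {
          f <- correlated_field(region$nrow, region$ncol, missing_corr_cells)
          fv <- f[cbind(region$cells$row, region$cells$col)]
          mask <- fv <= stats::quantile(fv, missing_fraction, type = 7)
          if (v == "day") day[mask, j] <- NA_real_ else night[mask, j] <- NA_real_
        }
      }
    }
    structure(list(day = day, night = night,
                   imputed_day = matrix(0L, n, nd),
                   imputed_night = matrix(0L, n, nd),
                   dates = truth$dates, year = truth$year,
                   slopes_by_day = s),
              class = "lst_stack")
  })
}

#' @export
print.lst_stack <- function(x, ...) {
  cat(sprintf("lst_stack: %d cells x %d days (%d)\n",
              nrow(x$day), ncol(x$day), x$year))
  cat(sprintf("  missing: day %.1f%%, night %.1f%%; imputed: day %.1f%%, night %.1f%%\n",
              100 * mean(is.na(x$day)), 100 * mean(is.na(x$night)),
              100 * mean(x$imputed_day), 100 * mean(x$imputed_night)))
  invisible(x)
}

#' Sample weather stations and their daily records from a synthetic truth
#'
#' Places stations at distinct grid cells, draws their daily observations as
#' truth-at-cell plus independent station noise, simulates mean wind speed,
#' and injects the requested quality violations *after* sampling so every
#' planted artifact is exactly labelled.
#'
#' @param truth A `ta_truth`.
#' @param n_stations Number of stations (<= number of cells).
#' @param networks data.frame with columns `name`, `frac` (station share),
#'   `crowdsourced` (logical). Default: two reference networks and one
#'   crowdsourced network.
#' @param violations List of planted-violation descriptors; each a list with
#'   `kind` (one of `short_record`, `impossible`, `implausible`,
#'   `stuck_run`, `gross_bias`), `station` (integer index), and
#'   kind-specific fields `date` (index into the year), `variable`,
#'   `magnitude`, `length`, `keep_n`.
#' @param seed Integer seed.
#' @param obs_sd Station observation noise SD, degC (default 0.5).
#' @param wind_mean,wind_sd Lognormal-ish wind distribution (absolute normal).
#' @param wind_missing Fraction of station-days with missing wind.
#' @param prediction_area_only Place stations only in prediction-area cells.
#' @return List with `meta` (station table incl. `cell_id`,
#'   `crowdsourced`, `in_prediction_area`), `records` (station-day rows:
#'   `station_id, network, date, tmin_c, tmean_c, tmax_c, wind_ms`), and
#'   `violations` (label table with the expected triggering check).
#' @export
sample_stations <- function(truth, n_stations = 50,
                            networks = data.frame(
                              name = c("AUT", "OBS", "CWS"),
                              frac = c(0.3, 0.2, 0.5),
                              crowdsourced = c(FALSE, FALSE, TRUE)),
                            violations = list(), seed = NULL,
                            obs_sd = 0.5, wind_mean = 3, wind_sd = 1.5,
                            wind_missing = 0.1,
                            prediction_area_only = FALSE) {
  cells <- truth$grid$cells
  pool <- if (prediction_area_only) which(cells$in_prediction_area) else seq_len(nrow(cells))
  if (n_stations > length(pool)) stop("n_stations exceeds the number of available cells")
  nd <- length(truth$dates)

  with_seed(seed, {
    cell_idx <- sample(pool, n_stations)
    counts <- diff(round(cumsum(c(0, networks$frac)) / sum(networks$frac) * n_stations))
    net <- rep(networks$name, counts)
    meta <- data.frame(
      station_id = sprintf("S%03d", seq_len(n_stations)),
      network = net,
      crowdsourced = networks$crowdsourced[match(net, networks$name)],
      lon = cells$lon[cell_idx], lat = cells$lat[cell_idx],
      elev_m = cells$elev_m[cell_idx],
      cell_id = cells$cell_id[cell_idx],
      in_prediction_area = cells$in_prediction_area[cell_idx]
    )

    records <- do.call(rbind, lapply(seq_len(n_stations), function(i) {
      noise <- if (obs_sd > 0) matrix(rnorm(nd * 3, 0, obs_sd), nd, 3) else matrix(0, nd, 3)
      wind <- abs(rnorm(nd, wind_mean, wind_sd))
      if (wind_missing > 0) wind[runif(nd) < wind_missing] <- NA_real_
      data.frame(
        station_id = meta$station_id[i], network = meta$network[i],
        date = truth$dates,
        tmin_c = truth$ta[cell_idx[i], , "tmin"] + noise[, 1],
        tmean_c = truth$ta[cell_idx[i], , "tmean"] + noise[, 2],
        tmax_c = truth$ta[cell_idx[i], , "tmax"] + noise[, 3],
        wind_ms = wind
      )
    }))
    rownames(records) <- NULL

    lab <- list()
    for (v in violations) {
      st <- meta$station_id[v$station]
      ri <- which(records$station_id == st)
      kind <- v$kind
      if (kind == "short_record") {
        keep <- sort(sample(nd, v$keep_n %||% 10L))
        drop <- ri[-keep]
        records <- records[-drop, , drop = FALSE]
        ri <- which(records$station_id == st)
        lab[[length(lab) + 1]] <- data.frame(
          station_id = st, date = records$date[ri], kind = kind,
          variable = "all", magnitude = NA_real_, expected_check = "a")
      } else if (kind == "impossible") {
        r <- ri[v$date]
        tmp <- records$tmin_c[r]
        records$tmin_c[r] <- records$tmax_c[r]
        records$tmax_c[r] <- tmp
        lab[[length(lab) + 1]] <- data.frame(
          station_id = st, date = records$date[r], kind = kind,
          variable = "tmin_tmax", magnitude = NA_real_, expected_check = "b")
      } else if (kind == "implausible") {
        r <- ri[v$date]
        var <- v$variable %||% "tmean_c"
        records[[var]][r] <- v$magnitude
        lab[[length(lab) + 1]] <- data.frame(
          station_id = st, date = records$date[r], kind = kind,
          variable = var, magnitude = v$magnitude, expected_check = "b")
      } else if (kind == "stuck_run") {
        len <- v$length %||% 5L
        r <- ri[v$date + seq_len(len) - 1L]
        var <- v$variable %||% "tmean_c"
        records[[var]][r] <- round(records[[var]][r[1]], 2)
        lab[[length(lab) + 1]] <- data.frame(
          station_id = st, date = records$date[r], kind = kind,
          variable = var, magnitude = len, expected_check = "c")
      } else if (kind == "gross_bias") {
        r <- ri[v$date]
        mag <- v$magnitude %||% 15
        for (var in c("tmin_c", "tmean_c", "tmax_c")) {
          records[[var]][r] <- records[[var]][r] + mag
        }
        lab[[length(lab) + 1]] <- data.frame(
          station_id = st, date = records$date[r], kind = kind,
          variable = "all", magnitude = mag, expected_check = "d")
      } else {
        stop("unknown violation kind: ", kind)
      }
    }
    labels <- if (length(lab)) do.call(rbind, lab) else
      data.frame(station_id = character(), date = as.Date(character()),
                 kind = character(), variable = character(),
                 magnitude = numeric(), expected_check = character())
    list(meta = meta, records = records, violations = labels)
  })
}

#' Plan a mixed set of planted violations
#'
#' Builds a violation list spanning all four quality checks, on distinct
#' stations so the checks do not interact, suitable for
#' [sample_stations()].
#'
#' @param n_stations Number of stations in the fixture.
#' @param n_days Days in the simulated year.
#' @param n Total number of violations.
#' @param seed Integer seed.
#' @param spike_pool Optional station indices eligible for `gross_bias`
#'   spikes (e.g. stations with enough buddy-check neighbours, see
#'   [eligible_neighbor_counts()]); other kinds are placed on the
#'   remaining stations.
#' @export
plant_violation_plan <- function(n_stations, n_days, n = 40, seed = NULL,
                                 spike_pool = NULL) {
  with_seed(seed, {
    kinds <- rep(c("impossible", "implausible", "stuck_run", "gross_bias",
                   "short_record"),
                 times = pmax(0, diff(round(seq(0, n, length.out = 6)))))
    kinds <- kinds[seq_len(n)]
    st <- integer(n)
    gb <- kinds == "gross_bias"
    if (!is.null(spike_pool) && any(gb)) {
      if (length(spike_pool) < sum(gb)) {
        stop("spike_pool smaller than the number of gross_bias violations")
      }
      st[gb] <- sample(spike_pool, sum(gb))
      st[!gb] <- sample(setdiff(seq_len(n_stations), st[gb]), sum(!gb))
    } else {
      st <- sample(n_stations, n)  # distinct stations
    }
    lapply(seq_len(n), function(i) {
      k <- kinds[i]
      base <- list(kind = k, station = st[i])
      if (k == "short_record") {
        base$keep_n <- sample(5:19, 1)
      } else if (k == "stuck_run") {
        base$variable <- sample(c("tmean_c", "tmin_c", "tmax_c"), 1)
        base$length <- if (base$variable == "tmean_c") sample(3:6, 1) else sample(4:7, 1)
        base$date <- sample(n_days - 10, 1)
      } else if (k == "implausible") {
        base$variable <- sample(c("tmean_c", "tmax_c", "wind_ms"), 1)
        base$magnitude <- switch(base$variable,
                                 tmean_c = -35, tmax_c = 60, wind_ms = 120)
        base$date <- sample(n_days, 1)
      } else {
        base$date <- sample(n_days, 1)
        if (k == "gross_bias") base$magnitude <- 15
      }
      base
    })
  })
}

#' Simulate responses from the calibration model itself
#'
#' Given a built design (see [build_design()]), generates the outcome as
#' `X beta + day random effects + residual`, where the random part has a
#' per-day intercept and per-day slopes on the standardized day/night LST
#' columns. Used for parameter-recovery and cross-validation calibration
#' studies where the model is exactly correctly specified.
#'
#' @param design Design data.frame from [build_design()] (standardized).
#' @param beta Named fixed-coefficient vector on the standardized scale;
#'   names must match the model-matrix columns of the calibration formula.
#' @param re_sd Length-3 SDs of the day random intercept and the day/night
#'   LST random slopes.
#' @param sigma Residual SD in degC.
#' @param seed Integer seed.
#' @return List: `design` with the `ta` column replaced by simulated values,
#'   `beta`, realised random effects `u` (days x 3), `sigma`.
#' @export
simulate_from_model <- function(design, beta, re_sd = c(2, 0.5, 0.5),
                                sigma = 1, seed = NULL) {
  X <- calibration_model_matrix(design)
  if (!all(names(beta) %in% colnames(X))) {
    stop("beta names not in model matrix columns: ",
         paste(setdiff(names(beta), colnames(X)), collapse = ", "))
  }
  with_seed(seed, {
    days <- sort(unique(design$day))
    u <- cbind(int = rnorm(length(days), 0, re_sd[1]),
               day_lst = rnorm(length(days), 0, re_sd[2]),
               night_lst = rnorm(length(days), 0, re_sd[3]))
    rownames(u) <- as.character(days)
    di <- match(design$day, days)
    eta <- as.vector(X[, names(beta), drop = FALSE] %*% beta) +
      u[di, "int"] + u[di, "day_lst"] * design$day_lst +
      u[di, "night_lst"] * design$night_lst
    design$ta <- eta + if (sigma > 0) rnorm(nrow(design), 0, sigma) else 0
    list(design = design, beta = beta, u = u, sigma = sigma)
  })
}
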