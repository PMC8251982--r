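# Two-satellite LST merge, within-year temporal gap-filling, and station
# wind-speed imputation.

#' Merge two satellites' LST stacks
#'
#' Cell-day-wise: when both satellites report, the average; when one is
#' missing, the other's value; when both are missing, the cell-day stays
#' missing (queued for temporal imputation). Provenance is recorded per
#' variable.
#'
#' @param sat1,sat2 `lst_stack` objects of identical shape (e.g. Terra-like
#'   and Aqua-like).
#' @return An `lst_stack` with `source_day`/`source_night` provenance
#'   matrices coded `both`, `sat1_only`, `sat2_only`, or `missing`.
#' @export
merge_satellites <- function(sat1, sat2) {
  if (!identical(dim(sat1$day), dim(sat2$day)) ||
      !identical(dim(sat1$night), dim(sat2$night))) {
    stop("satellite stacks have mismatched shapes")
  }
  merge_one <- function(a, b) {
    val <- (ifelse(is.na(a), 0, a) + ifelse(is.na(b), 0, b)) /
      ((!is.na(a)) + (!is.na(b)))
    val[is.na(a) & is.na(b)] <- NA_real_
    src <- matrix("missing", nrow(a), ncol(a))
    src[!is.na(a) & !is.na(b)] <- "both"
    src[!is.na(a) & is.na(b)] <- "sat1_only"
    src[is.na(a) & !is.na(b)] <- "sat2_only"
    list(val = val, src = src)
  }
  d <- merge_one(sat1$day, sat2$day)
  n <- merge_one(sat1$night, sat2$night)
  structure(list(day = d$val, night = n$val,
                 source_day = d$src, source_night = n$src,
                 imputed_day = matrix(0L, nrow(d$val), ncol(d$val)),
                 imputed_night = matrix(0L, nrow(n$val), ncol(n$val)),
                 dates = sat1$dates, year = sat1$year),
            class = "lst_stack")
}

#' Temporal gap-filling of one cell's within-year LST series
#'
#' Interior gaps on day `t` are filled from the closest observed days
#' before (`t0`, value `y0`) and after (`t1`, value `y1`) in the same year
#' as `y = (y0 * (t1 - t) + y1 * (t - t0)) / (t1 - t0)`. When no earlier
#' observation exists the next observed value is used unaltered; likewise
#' the previous observed value for trailing gaps. Interpolation never
#' crosses year boundaries (the series is one year by construction).
#'
#' @param y Numeric series over consecutive days of one year (`NA` =
#'   missing).
#' @return List: `values` (gap-filled series; all-`NA` input stays `NA`),
#'   `imputed` (integer indicators, 1 exactly on filled days).
#' @export
impute_lst_temporal <- function(y) {
  n <- length(y)
  obs <- which(!is.na(y))
  imputed <- as.integer(is.na(y))
  if (length(obs) == 0) {
    return(list(values = y, imputed = imputed, unavailable = TRUE))
  }
  t <- seq_len(n)
  # index of the closest observed day at or before t (0 if none) and the
  # first observed day at or after t (length(obs)+1 if none)
  prev <- findInterval(t, obs)
  nxt <- findInterval(t - 1L, obs) + 1L
  out <- y
  gap <- is.na(y)
  lead <- gap & prev == 0
  trail <- gap & nxt > length(obs)
  interior <- gap & !lead & !trail
  out[lead] <- y[obs[1]]
  out[trail] <- y[obs[length(obs)]]
  if (any(interior)) {
    t0 <- obs[prev[interior]]
    t1 <- obs[nxt[interior]]
    ti <- t[interior]
    out[interior] <- (y[t0] * (t1 - ti) + y[t1] * (ti - t0)) / (t1 - t0)
  }
  list(values = out, imputed = imputed, unavailable = FALSE)
}

#' Gap-fill a merged LST stack
#'
#' Applies [impute_lst_temporal()] to every cell's day and night series and
#' sets the imputation indicator matrices. Cells with zero observations in
#' the year remain missing and are counted as unavailable.
#'
#' @param stack A merged `lst_stack`.
#' @return The stack with gaps filled, `imputed_day`/`imputed_night` set,
#'   and `unavailable_day`/`unavailable_night` cell counts attached.
#' @export
gapfill_lst <- function(stack) {
  fill <- function(m, ind) {
    unavail <- 0L
    for (i in seq_len(nrow(m))) {
      if (!anyNA(m[i, ])) next
      r <- impute_lst_temporal(m[i, ])
      m[i, ] <- r$values
      ind[i, ] <- r$imputed
      if (isTRUE(r$unavailable)) unavail <- unavail + 1L
    }
    list(m = m, ind = ind, unavail = unavail)
  }
  d <- fill(stack$day, stack$imputed_day)
  n <- fill(stack$night, stack$imputed_night)
  stack$day <- d$m; stack$imputed_day <- d$ind
  stack$night <- n$m; stack$imputed_night <- n$ind
  stack$unavailable_day <- d$unavail
  stack$unavailable_night <- n$unavail
  stack
}

#' Impute a station's missing mean wind speed
#'
#' Takes the wind speed of the closest station (great-circle distance) with
#' a value on the same day; if no station has one that day, steps back one
#' day at a time (up to `max_back_days`) until a donor exists. Distance
#' ties break by station id.
#'
#' @param records Station-day data.frame of candidate donors
#'   (`station_id`, `date`, `wind_ms`).
#' @param station_meta Station table with coordinates.
#' @param target_station Station id being imputed (excluded as donor).
#' @param day `Date` of the missing value.
#' @param max_back_days Back-search cap before failing.
#' @return The donor wind value (m/s).
#' @export
impute_wind <- function(records, station_meta, target_station, day,
                        max_back_days = 30) {
  tgt <- station_meta[station_meta$station_id == target_station, ]
  if (nrow(tgt) != 1) stop("unknown target station: ", target_station)
  for (back in 0:max_back_days) {
    d <- day - back
    cand <- records[records$date == d & !is.na(records$wind_ms) &
                      records$station_id != target_station, ]
    if (nrow(cand) == 0) next
    dm <- station_meta[match(cand$station_id, station_meta$station_id), ]
    dk <- dist_km(tgt$lon, tgt$lat, dm$lon, dm$lat)
    ord <- order(dk, cand$station_id)
    return(cand$wind_ms[ord[1]])
  }
  stop(sprintf("no wind donor found for station %s on %s (searched %d days back)",
               target_station, format(day), max_back_days))
}

# Vectorised wind fill: returns records with missing wind imputed from
# `donor_records` (defaults to the records themselves). `force_all` imputes
# every row as if its own wind were missing (the held-out-station rule).
fill_wind <- function(records, station_meta, donor_records = records,
                      max_back_days = 30, force_all = FALSE) {
  need <- if (force_all) seq_len(nrow(records)) else which(is.na(records$wind_ms))
  if (length(need) == 0) return(records)
  all_dates <- sort(unique(c(records$date, donor_records$date)))
  sm <- station_meta
  Wm <- matrix(NA_real_, nrow(sm), length(all_dates))
  dsi <- match(donor_records$station_id, sm$station_id)
  ddi <- match(donor_records$date, all_dates)
  ok <- !is.na(donor_records$wind_ms) & !is.na(dsi)
  Wm[cbind(dsi[ok], ddi[ok])] <- donor_records$wind_ms[ok]
  D <- dist_matrix_km(sm$lon, sm$lat)
  diag(D) <- Inf
  # tie-break on station id: add a tiny id-ordered epsilon
  eps <- outer(rep(1, nrow(sm)), rank(sm$station_id)) * 1e-9
  Dt <- D + eps

  ti <- match(records$station_id[need], sm$station_id)
  di <- match(records$date[need], all_dates)
  for (k in seq_along(need)) {
    tgt <- ti[k]
    val <- NA_real_
    for (back in 0:max_back_days) {
      j <- di[k] - back
      if (j < 1) break
      donors <- which(!is.na(Wm[, j]))
      donors <- donors[donors != tgt]
      if (length(donors)) {
        val <- Wm[donors[which.min(Dt[tgt, donors])], j]
        break
      }
    }
    if (is.na(val)) {
      stop(sprintf("no wind donor found for station %s on %s",
                   records$station_id[need[k]], format(records$date[need[k]])))
    }
    records$wind_ms[need[k]] <- val
  }
  records
}
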