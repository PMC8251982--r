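# Quality-assessment cascade for heterogeneous station networks.
#
# Four sequential checks: (a) minimum yearly record length, (b) physical /
# climatological limits, (c) stuck (repeated-value) runs, (d) spatial
# consistency ("buddy check") against inverse-distance-weighted
# interpolations from nearby, elevation-similar stations.

#' Buddy-check configuration
#'
#' @param max_distance_km Neighbour search radius (km).
#' @param max_elev_diff_m Maximum elevation difference for neighbours (m).
#' @param percentile Deviation percentile defining the flagging threshold.
#' @param station_drop_fraction Fraction of flagged temperature-days at or
#'   above which a whole station(-year) is dropped.
#' @param idw_power Inverse-distance weight exponent.
#' @param min_neighbors Minimum qualifying neighbours for an interpolation.
#' @export
buddy_config <- function(max_distance_km = 30, max_elev_diff_m = 500,
                         percentile = 99, station_drop_fraction = 0.20,
                         idw_power = 2, min_neighbors = 3) {
  stopifnot(max_distance_km > 0, max_elev_diff_m > 0,
            percentile > 0, percentile <= 100,
            station_drop_fraction > 0)
  structure(list(max_distance_km = max_distance_km,
                 max_elev_diff_m = max_elev_diff_m,
                 percentile = percentile,
                 station_drop_fraction = station_drop_fraction,
                 idw_power = idw_power,
                 min_neighbors = min_neighbors),
            class = "buddy_config")
}

#' Check (a): minimum observations per station-year
#'
#' Flags every station-day of any (station, year) with fewer than `min_n`
#' station-days on record.
#'
#' @param records Station-day data.frame (`station_id`, `date`, ...).
#' @param min_n Minimum station-days per station-year.
#' @return Logical vector, one element per row of `records`.
#' @export
check_min_observations <- function(records, min_n = 20) {
  if (nrow(records) == 0) return(logical(0))
  key <- paste(records$station_id, format(records$date, "%Y"))
  cnt <- table(key)
  as.vector(cnt[key] < min_n)
}

#' Check (b): physically impossible or climatologically implausible values
#'
#' Flags station-days with a maximum below the minimum, negative wind, any
#' temperature colder than -30 degC or hotter than 53 degC, or mean wind
#' speed greater than 114 m/s (all strict inequalities).
#'
#' @param records Station-day data.frame.
#' @return Logical vector per row.
#' @export
check_physical_limits <- function(records) {
  lo <- -30; hi <- 53; wmax <- 114
  bad_t <- function(v) !is.na(v) & (v < lo | v > hi)
  impossible <- (!is.na(records$tmax_c) & !is.na(records$tmin_c) &
                   records$tmax_c < records$tmin_c) |
    (!is.na(records$wind_ms) & records$wind_ms < 0)
  implausible <- bad_t(records$tmin_c) | bad_t(records$tmean_c) |
    bad_t(records$tmax_c) |
    (!is.na(records$wind_ms) & records$wind_ms > wmax)
  impossible | implausible
}

#' Check (c): stuck runs of repeated values
#'
#' Flags maximal runs of equal values (after rounding to the nearest
#' 0.01 degC) longer than the allowed run length, per temperature variable,
#' counting over observed days only. Runs of up to `max_run_mean` equal
#' values are allowed for the daily mean and up to `max_run_minmax` for the
#' minimum and maximum.
#'
#' @param records Station-day data.frame, any row order.
#' @param max_run_mean,max_run_minmax Longest permitted runs.
#' @return Logical matrix (rows of `records` x `tmin_c`,`tmean_c`,`tmax_c`).
#' @export
check_stuck_runs <- function(records, max_run_mean = 2, max_run_minmax = 3) {
  vars <- c(tmin_c = max_run_minmax, tmean_c = max_run_mean,
            tmax_c = max_run_minmax)
  out <- matrix(FALSE, nrow(records), 3,
                dimnames = list(NULL, names(vars)))
  if (nrow(records) == 0) return(out)
  ord <- order(records$station_id, records$date)
  for (v in names(vars)) {
    val <- round(records[[v]][ord], 2)
    st <- records$station_id[ord]
    obs <- !is.na(val)
    idx <- ord[obs]
    r <- rle(paste(st[obs], val[obs]))
    flag_run <- r$lengths > vars[[v]]
    out[idx[rep(flag_run, r$lengths)], v] <- TRUE
  }
  out
}

#' Inverse-distance-weighted interpolation from neighbouring stations
#'
#' Interpolates a station's value from same-day neighbours within the
#' configured distance and elevation window, with weights
#' `distance^(-idw_power)`. A neighbour at zero distance dominates the
#' interpolation (exact-match weight). Returns `NA` when fewer than
#' `min_neighbors` neighbours qualify.
#'
#' @param values Neighbour observations.
#' @param dist_km Neighbour distances from the target (km).
#' @param elev_diff_m Absolute elevation differences (m); optional.
#' @param config A [buddy_config()].
#' @return The interpolated value, or `NA_real_`.
#' @export
idw_interpolate <- function(values, dist_km, elev_diff_m = NULL,
                            config = buddy_config()) {
  keep <- !is.na(values) & dist_km <= config$max_distance_km
  if (!is.null(elev_diff_m)) keep <- keep & abs(elev_diff_m) <= config$max_elev_diff_m
  values <- values[keep]; dist_km <- dist_km[keep]
  if (length(values) < config$min_neighbors) return(NA_real_)
  w <- ifelse(dist_km <= 0, 1e12, dist_km^(-config$idw_power))
  sum(w * values) / sum(w)
}

#' Check (d): buddy check for spatial consistency
#'
#' Compares each observation to the IDW interpolation from qualifying
#' neighbours on the same day. Deviations are the squared differences
#' between observations and interpolations; per outcome and per year the
#' flagging threshold is the 99th percentile of the deviations over
#' non-crowdsourced stations. A station-day whose deviation exceeds the
#' threshold for any outcome is flagged; stations(-years) with
#' `station_drop_fraction` or more of their evaluable temperature-days
#' flagged are dropped entirely.
#'
#' @param records Station-day data.frame.
#' @param station_meta Station table with `station_id`, `lon`, `lat`,
#'   `elev_m`, `crowdsourced`.
#' @param config A [buddy_config()].
#' @return List: `day_flag` (logical per row), `station_drop` (logical per
#'   row), `thresholds` (per outcome/year), `deviations` (long data.frame),
#'   `n_skipped` (station-day/outcome combinations with too few
#'   neighbours).
#' @export
buddy_check <- function(records, station_meta, config = buddy_config()) {
  n <- nrow(records)
  empty <- list(day_flag = logical(n), station_drop = logical(n),
                thresholds = NULL, deviations = NULL, n_skipped = 0L)
  if (n == 0) return(empty)
  meta <- station_meta[match(unique(records$station_id), station_meta$station_id), ]
  ns <- nrow(meta)
  D <- dist_matrix_km(meta$lon, meta$lat)
  Ed <- outer(meta$elev_m, meta$elev_m, function(a, b) abs(a - b))
  E <- D <= config$max_distance_km & Ed <= config$max_elev_diff_m
  diag(E) <- FALSE
  W <- matrix(0, ns, ns)
  W[E] <- ifelse(D[E] <= 0, 1e12, D[E]^(-config$idw_power))

  dates <- sort(unique(records$date))
  si <- match(records$station_id, meta$station_id)
  di <- match(records$date, dates)
  years <- as.integer(format(records$date, "%Y"))
  crowd <- meta$crowdsourced[si]

  vars <- c("tmin_c", "tmean_c", "tmax_c")
  dev <- matrix(NA_real_, n, 3, dimnames = list(NULL, vars))
  n_skipped <- 0L
  Emat <- E * 1
  for (v in vars) {
    V <- matrix(NA_real_, ns, length(dates))
    V[cbind(si, di)] <- records[[v]]
    M <- !is.na(V)
    V0 <- ifelse(M, V, 0)
    NUM <- W %*% V0
    DEN <- W %*% M
    CNT <- Emat %*% M
    interp <- ifelse(CNT >= config$min_neighbors & DEN > 0, NUM / DEN, NA_real_)
    obs <- records[[v]]
    itp <- interp[cbind(si, di)]
    dev[, v] <- (obs - itp)^2
    n_skipped <- n_skipped + sum(!is.na(obs) & is.na(itp))
  }

  thr <- do.call(rbind, lapply(sort(unique(years)), function(yr) {
    ref <- years == yr & !crowd
    data.frame(year = yr,
               tmin_c = safe_quantile(dev[ref, "tmin_c"], config$percentile / 100),
               tmean_c = safe_quantile(dev[ref, "tmean_c"], config$percentile / 100),
               tmax_c = safe_quantile(dev[ref, "tmax_c"], config$percentile / 100))
  }))
  yi <- match(years, thr$year)
  over <- sapply(vars, function(v) !is.na(dev[, v]) & dev[, v] > thr[[v]][yi])
  day_flag <- rowSums(over) > 0

  # station(-year) drop rule: denominator = station-days with at least one
  # computable deviation in that year
  evaluable <- rowSums(!is.na(dev)) > 0
  key <- paste(records$station_id, years)
  frac <- tapply(day_flag[evaluable], key[evaluable], mean)
  dropped_keys <- names(frac)[!is.na(frac) & frac >= config$station_drop_fraction]
  station_drop <- key %in% dropped_keys

  deviations <- data.frame(station_id = records$station_id,
                           date = records$date, dev)
  list(day_flag = day_flag, station_drop = station_drop,
       thresholds = thr, deviations = deviations, n_skipped = n_skipped)
}

#' Count qualifying buddy-check neighbours per station
#'
#' Number of other stations within the configured distance and elevation
#' window; stations below `min_neighbors` cannot be evaluated by the buddy
#' check.
#'
#' @param station_meta Station table with `lon`, `lat`, `elev_m`.
#' @param config A [buddy_config()].
#' @return Integer vector, one count per station.
#' @export
eligible_neighbor_counts <- function(station_meta, config = buddy_config()) {
  D <- dist_matrix_km(station_meta$lon, station_meta$lat)
  Ed <- outer(station_meta$elev_m, station_meta$elev_m,
              function(a, b) abs(a - b))
  E <- D <= config$max_distance_km & Ed <= config$max_elev_diff_m
  diag(E) <- FALSE
  rowSums(E)
}

safe_quantile <- function(x, p) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::quantile(x, p, type = 7, names = FALSE)
}

#' Detect candidate duplicate stations
#'
#' Reports pairs of stations within `radius_m` of each other whose shared
#' days have at least `min_identical_fraction` identical daily means (after
#' 0.01 degC rounding). Report-only: nothing is dropped.
#'
#' @param station_meta Station table.
#' @param records Station-day data.frame.
#' @param radius_m Location radius (default 100 m).
#' @param min_identical_fraction Minimum identical fraction (default 0.5).
#' @param min_shared_days Minimum overlapping days to consider a pair.
#' @return data.frame of candidate pairs with shared-day counts and the
#'   identical fraction (possibly empty).
#' @export
detect_duplicate_stations <- function(station_meta, records, radius_m = 100,
                                      min_identical_fraction = 0.5,
                                      min_shared_days = 10) {
  out <- list()
  ns <- nrow(station_meta)
  if (ns >= 2) {
    D <- dist_matrix_km(station_meta$lon, station_meta$lat) * 1000
    for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
      if (D[i, j] > radius_m) next
      a <- records[records$station_id == station_meta$station_id[i], ]
      b <- records[records$station_id == station_meta$station_id[j], ]
      m <- merge(a[, c("date", "tmean_c")], b[, c("date", "tmean_c")], by = "date")
      m <- m[!is.na(m$tmean_c.x) & !is.na(m$tmean_c.y), ]
      if (nrow(m) < min_shared_days) next
      frac <- mean(round(m$tmean_c.x, 2) == round(m$tmean_c.y, 2))
      if (frac >= min_identical_fraction) {
        out[[length(out) + 1]] <- data.frame(
          station_a = station_meta$station_id[i],
          station_b = station_meta$station_id[j],
          distance_m = D[i, j], shared_days = nrow(m),
          identical_fraction = frac)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(station_a = character(), station_b = character(),
               distance_m = numeric(), shared_days = integer(),
               identical_fraction = numeric())
}

#' Run the full quality-assessment cascade
#'
#' Applies checks (a)-(d) sequentially, each on the survivors of the
#' previous one. Checks (a), (b), and (d) drop whole station-days (check
#' (d) can drop whole stations); check (c) removes only the offending
#' temperature variable.
#'
#' @param records Station-day data.frame.
#' @param station_meta Station table (see [buddy_check()]).
#' @param config A [buddy_config()].
#' @param min_obs Check (a) threshold.
#' @param max_run_mean,max_run_minmax Check (c) run limits.
#' @return List of class `qa_report`: `records` (cleaned survivors),
#'   `flags` (long table: station_id, date, check, variable), `audit`
#'   (named per-check dropped counts plus totals), `thresholds` (buddy),
#'   `duplicates` (report-only candidate table).
#' @export
run_qa <- function(records, station_meta, config = buddy_config(),
                   min_obs = 20, max_run_mean = 2, max_run_minmax = 3) {
  flags <- list()
  note <- function(rows, check, variable = "all") {
    if (length(rows) == 0 || !any(rows)) return(NULL)
    data.frame(station_id = records$station_id[rows],
               date = records$date[rows], check = check, variable = variable)
  }

  # (a) minimum observations per station-year
  fa <- check_min_observations(records, min_obs)
  flags$a <- note(fa, "a_min_obs")
  n_a <- sum(fa)
  records <- records[!fa, , drop = FALSE]

  # (b) physical limits
  fb <- check_physical_limits(records)
  flags$b <- note(fb, "b_limits")
  n_b <- sum(fb)
  records <- records[!fb, , drop = FALSE]

  # (c) stuck runs: per-variable removal
  fc <- check_stuck_runs(records, max_run_mean, max_run_minmax)
  n_c <- sum(fc)
  for (v in colnames(fc)) {
    flags[[paste0("c_", v)]] <- note(fc[, v], "c_stuck_run", v)
    records[[v]][fc[, v]] <- NA_real_
  }
  all_na <- is.na(records$tmin_c) & is.na(records$tmean_c) & is.na(records$tmax_c)
  records <- records[!all_na, , drop = FALSE]

  # (d) buddy check
  bd <- buddy_check(records, station_meta, config)
  fd <- bd$day_flag & !bd$station_drop
  fdrop <- bd$station_drop
  flags$d <- note(fd, "d_buddy")
  flags$d_drop <- note(fdrop, "d_station_drop")
  n_d <- sum(bd$day_flag | fdrop)
  records <- records[!(bd$day_flag | fdrop), , drop = FALSE]

  dup <- detect_duplicate_stations(station_meta, records)

  flag_tab <- do.call(rbind, Filter(Negate(is.null), flags))
  rownames(records) <- rownames(flag_tab) <- NULL
  audit <- list(a_min_obs = n_a, b_limits = n_b, c_stuck_run = n_c,
                d_buddy = n_d, buddy_skipped = bd$n_skipped,
                total_dropped = n_a + n_b + n_d,
                remaining = nrow(records))
  structure(list(records = records, flags = flag_tab, audit = audit,
                 thresholds = bd$thresholds, duplicates = dup),
            class = "qa_report")
}

#' @export
print.qa_report <- function(x, ...) {
  a <- x$audit
  cat("Station quality assessment\n")
  cat(sprintf("  (a) (%d) station-years with too few observations\n", a$a_min_obs))
  cat(sprintf("  (b) (%d) impossible or implausible station-days\n", a$b_limits))
  cat(sprintf("  (c) (%d) stuck-run values removed\n", a$c_stuck_run))
  cat(sprintf("  (d) (%d) buddy-check station-days (incl. station drops)\n", a$d_buddy))
  cat(sprintf("  remaining station-days: %d\n", a$remaining))
  if (nrow(x$duplicates)) {
    cat(sprintf("  candidate duplicate pairs: %d (report-only)\n", nrow(x$duplicates)))
  }
  invisible(x)
}
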