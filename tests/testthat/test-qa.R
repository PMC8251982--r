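# Quality-assessment cascade: checks (a)-(d) plus duplicate detection.

mk_records <- function(station_id, dates, tmin = 10, tmean = 15, tmax = 20,
                       wind = 3, network = "AUT") {
  data.frame(station_id = station_id, network = network, date = dates,
             tmin_c = tmin, tmean_c = tmean, tmax_c = tmax, wind_ms = wind)
}

test_that("check (a) flags station-years with fewer than 20 observations", {
  d18 <- seq(as.Date("2018-01-01"), by = "day", length.out = 19)
  r <- mk_records("A", d18)
  expect_true(all(check_min_observations(r)))

  r20 <- mk_records("A", seq(as.Date("2018-01-01"), by = "day", length.out = 20))
  expect_false(any(check_min_observations(r20)))

  # per-year scoping: short 2017, long 2018
  r2 <- rbind(mk_records("A", seq(as.Date("2017-06-01"), by = "day", length.out = 19)),
              mk_records("A", seq(as.Date("2018-01-01"), by = "day", length.out = 300)))
  f <- check_min_observations(r2)
  expect_equal(sum(f), 19)
  expect_true(all(format(r2$date[f], "%Y") == "2017"))
})

test_that("check (b) catches impossible and implausible station-days", {
  d <- as.Date("2018-05-01")
  expect_true(check_physical_limits(mk_records("A", d, tmin = 25, tmax = 20)))
  expect_true(check_physical_limits(mk_records("A", d, tmean = -35)))
  expect_true(check_physical_limits(mk_records("A", d, tmax = 54)))
  expect_true(check_physical_limits(mk_records("A", d, wind = -0.1)))
  # strict inequality on the wind cap
  expect_false(check_physical_limits(mk_records("A", d, wind = 114.0)))
  expect_true(check_physical_limits(mk_records("A", d, wind = 114.5)))
  expect_false(check_physical_limits(mk_records("A", d, tmean = -30)))
})

test_that("check (c) flags runs beyond the per-variable limits", {
  d <- seq(as.Date("2018-01-01"), by = "day", length.out = 6)
  base <- mk_records("A", d, tmean = c(20, 20, 20, 18, 19, 21),
                     tmin = 10 + (1:6) / 10, tmax = 30 + (1:6) / 10)
  f <- check_stuck_runs(base)
  expect_equal(which(f[, "tmean_c"]), 1:3)
  expect_false(any(f[, "tmin_c"]))

  # three equal tmin kept, four flagged
  r3 <- mk_records("A", d, tmin = c(5, 5, 5, 6, 7, 8), tmean = 15 + (1:6) / 10,
                   tmax = 30 + (1:6) / 10)
  expect_false(any(check_stuck_runs(r3)[, "tmin_c"]))
  r4 <- mk_records("A", d, tmin = c(5, 5, 5, 5, 7, 8), tmean = 15 + (1:6) / 10,
                   tmax = 30 + (1:6) / 10)
  expect_equal(which(check_stuck_runs(r4)[, "tmin_c"]), 1:4)

  # equality after rounding to the nearest 0.01
  rr <- mk_records("A", d[1:3], tmean = c(20.001, 20.004, 20.0),
                   tmin = c(1, 2, 3), tmax = c(30, 31, 32))
  expect_equal(which(check_stuck_runs(rr)[, "tmean_c"]), 1:3)

  # unobserved days are ignored, runs span the gap
  gap <- mk_records("A", d[c(1, 2, 4)], tmean = 20, tmin = c(1, 2, 3),
                    tmax = c(30, 31, 32))
  expect_true(all(check_stuck_runs(gap)[, "tmean_c"]))

  # runs do not cross stations
  two <- rbind(mk_records("A", d[1:2], tmean = 20, tmin = c(1, 2), tmax = c(30, 31)),
               mk_records("B", d[1:2], tmean = 20, tmin = c(1, 2), tmax = c(30, 31)))
  expect_false(any(check_stuck_runs(two)[, "tmean_c"]))
})

test_that("IDW interpolation weights, filters, and degenerate cases", {
  cfg1 <- buddy_config(min_neighbors = 1)
  # one qualifying neighbour -> its value
  expect_equal(idw_interpolate(12, 10, config = cfg1), 12)
  # equidistant neighbours -> plain mean
  expect_equal(idw_interpolate(c(10, 20), c(8, 8), config = cfg1), 15)
  # inverse-square weighting
  expect_equal(idw_interpolate(c(10, 20), c(10, 20), config = cfg1),
               (10 / 100 + 20 / 400) / (1 / 100 + 1 / 400))
  # neighbour beyond 30 km is excluded
  expect_equal(idw_interpolate(c(10, 99), c(8, 31), config = cfg1), 10)
  # elevation window applies
  expect_equal(idw_interpolate(c(10, 99), c(8, 8), elev_diff_m = c(100, 600),
                               config = cfg1), 10)
  # too few neighbours -> absent
  expect_true(is.na(idw_interpolate(c(10, 20), c(8, 8), config = buddy_config())))
  # zero-distance neighbour dominates
  expect_equal(idw_interpolate(c(7, 20), c(0, 5), config = cfg1), 7,
               tolerance = 1e-6)
})

test_that("buddy check flags spikes, drops bad stations, thresholds from reference networks", {
  fx <- fx_small()
  rec <- fx$stations$records
  meta <- fx$stations$meta

  bd <- buddy_check(rec, meta)
  # threshold equals the type-7 99th percentile of non-crowdsourced
  # deviations (independent recomputation)
  dv <- bd$deviations
  crowd <- meta$crowdsourced[match(dv$station_id, meta$station_id)]
  for (v in c("tmin_c", "tmean_c", "tmax_c")) {
    oracle <- quantile(dv[[v]][!crowd], 0.99, type = 7, names = FALSE, na.rm = TRUE)
    expect_equal(bd$thresholds[[v]], oracle, tolerance = 1e-12)
  }

  # a station spiking on >= 20% of its days is dropped entirely
  victim <- meta$station_id[which(eligible_neighbor_counts(meta) >= 3)[1]]
  rec2 <- rec
  vi <- which(rec2$station_id == victim)[1:95]
  for (v in c("tmin_c", "tmean_c", "tmax_c")) rec2[[v]][vi] <- rec2[[v]][vi] + 15
  bd2 <- buddy_check(rec2, meta)
  expect_true(all(bd2$station_drop[rec2$station_id == victim]))
})

test_that("duplicate stations are reported but never auto-dropped", {
  fx <- fx_small()
  meta <- fx$stations$meta
  rec <- fx$stations$records
  # clone one station under a new id at the same coordinates
  clone_meta <- meta[1, ]
  clone_meta$station_id <- "DUP"
  m2 <- rbind(meta, clone_meta)
  cr <- rec[rec$station_id == meta$station_id[1], ]
  cr$station_id <- "DUP"
  r2 <- rbind(rec, cr)
  dup <- detect_duplicate_stations(m2, r2)
  expect_true(any(dup$station_a == meta$station_id[1] & dup$station_b == "DUP" |
                    dup$station_b == meta$station_id[1] & dup$station_a == "DUP"))

  # stations far apart are never reported
  expect_false(any(dup$distance_m > 100))

  # same coordinates but different values -> not reported
  cr2 <- cr
  cr2$station_id <- "DUP2"
  cr2$tmean_c <- cr2$tmean_c + seq(1, 2, length.out = nrow(cr2))
  m3 <- rbind(m2, transform(clone_meta, station_id = "DUP2"))
  dup2 <- detect_duplicate_stations(m3, rbind(rec, cr2))
  expect_false(any(dup2$station_a == "DUP2" | dup2$station_b == "DUP2"))
})

test_that("run_qa applies the cascade in order and reports its audit", {
  fx <- fx_small()
  qa <- run_qa(fx$stations$records, fx$stations$meta)
  # clean fixture: deterministic checks drop nothing
  expect_equal(qa$audit$a_min_obs, 0)
  expect_equal(qa$audit$b_limits, 0)
  expect_equal(qa$audit$c_stuck_run, 0)
  expect_equal(qa$audit$total_dropped + qa$audit$remaining,
               nrow(fx$stations$records))

  # idempotence: a second pass drops nothing for (a)-(c) and only a
  # small percentile-tail fraction for (d)
  qa2 <- run_qa(qa$records, fx$stations$meta)
  expect_equal(qa2$audit$a_min_obs, 0)
  expect_equal(qa2$audit$b_limits, 0)
  expect_equal(qa2$audit$c_stuck_run, 0)
  expect_lt(qa2$audit$d_buddy / nrow(qa$records), 0.08)
})
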