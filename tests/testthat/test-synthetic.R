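# Synthetic region, truth, LST, and station generators.

test_that("generators are deterministic under a fixed seed", {
  r1 <- simulate_region(10, 12, seed = 7)
  r2 <- simulate_region(10, 12, seed = 7)
  expect_identical(r1, r2)

  t1 <- simulate_truth(r1, 2015, seed = 8)
  t2 <- simulate_truth(r1, 2015, seed = 8)
  expect_identical(t1$ta, t2$ta)

  l1 <- simulate_lst(t1, missing_fraction = 0.2, seed = 9)
  l2 <- simulate_lst(t1, missing_fraction = 0.2, seed = 9)
  expect_identical(l1$day, l2$day)

  s1 <- sample_stations(t1, 12, seed = 10)
  s2 <- sample_stations(t1, 12, seed = 10)
  expect_identical(s1$records, s2$records)
})

test_that("region fields respect their ranges and have spatial structure", {
  r <- simulate_region(12, 12, seed = 21)
  expect_true(all(r$ndvi >= -1 & r$ndvi <= 1))
  expect_gt(var(r$cells$elev_m), 0)
  expect_true(all(r$cells$elev_m >= 1400 & r$cells$elev_m <= 4500))
  expect_error(simulate_region(4, 20), "rows and cols")
})

test_that("truth outcomes are ordered and the noise-free limit is exact", {
  fx <- fx_small()
  ta <- fx$truth$ta
  expect_true(all(ta[, , "tmin"] <= ta[, , "tmean"]))
  expect_true(all(ta[, , "tmean"] <= ta[, , "tmax"]))

  # all randomness off -> tmean equals the deterministic linear predictor
  r <- simulate_region(10, 10, seed = 31)
  tr <- simulate_truth(r, 2018, seed = 32, day_intercept_sd = 0,
                       residual_sd = 0, gap_log_sd = 0)
  p <- tr$params
  nd <- 365
  tt <- (seq_len(nd) - 1) / (nd - 1)
  month <- as.integer(format(tr$dates, "%m"))
  for (j in c(1, 100, 365)) {
    expected <- p$intercept + p$lapse * r$cells$elev_m +
      p$sin_coef * sin(2 * pi * tt[j]) + p$cos_coef * cos(2 * pi * tt[j]) +
      p$ndvi_coef * r$ndvi[, month[j]]
    expect_equal(tr$ta[, j, "tmean"], expected, tolerance = 1e-12)
    expect_equal(tr$ta[, j, "tmin"], expected - p$gap_min, tolerance = 1e-12)
  }
})

test_that("a negative elevation lapse shows up as negative correlation", {
  fx <- fx_small()
  day50 <- fx$truth$ta[, 50, "tmean"]
  expect_lt(cor(fx$region$cells$elev_m, day50), 0)
})

test_that("leap years produce 366 daily fields", {
  r <- simulate_region(8, 8, seed = 41)
  tr <- simulate_truth(r, 2004, seed = 42)
  expect_equal(dim(tr$ta)[2], 366)
  expect_equal(length(tr$dates), 366)
})

test_that("LST missingness hits its target and the identity map is exact", {
  r <- simulate_region(12, 12, seed = 51)
  tr <- simulate_truth(r, 2018, seed = 52)
  l0 <- simulate_lst(tr, missing_fraction = 0, seed = 53)
  expect_false(anyNA(l0$day))

  l3 <- simulate_lst(tr, missing_fraction = 0.3, seed = 54)
  frac_day <- mean(is.na(l3$day))
  frac_night <- mean(is.na(l3$night))
  expect_true(frac_day >= 0.25 && frac_day <= 0.35)
  expect_true(frac_night >= 0.25 && frac_night <= 0.35)

  ident <- simulate_lst(tr, slopes_by_day = list(a_day = 0, b_day = 1,
                                                 a_night = 0, b_night = 1),
                        noise_sd = 0, missing_fraction = 0, seed = 55,
                        basis = c(day = "tmean", night = "tmean"))
  expect_equal(ident$day, tr$ta[, , "tmean"], tolerance = 1e-12)
  expect_equal(ident$night, tr$ta[, , "tmean"], tolerance = 1e-12)

  expect_error(simulate_lst(tr, missing_fraction = 0.95), "missing_fraction")
})

test_that("stations reproduce truth at zero noise and label plants exactly", {
  r <- simulate_region(10, 10, seed = 61)
  tr <- simulate_truth(r, 2018, seed = 62)
  st0 <- sample_stations(tr, 8, seed = 63, obs_sd = 0)
  ci <- match(st0$meta$cell_id, r$cells$cell_id)
  for (i in c(1, 5)) {
    rows <- st0$records$station_id == st0$meta$station_id[i]
    expect_equal(st0$records$tmean_c[rows], tr$ta[ci[i], , "tmean"],
                 tolerance = 1e-12)
  }

  viol <- list(list(kind = "stuck_run", station = 2, date = 100,
                    variable = "tmean_c", length = 5),
               list(kind = "impossible", station = 3, date = 40))
  st <- sample_stations(tr, 8, violations = viol, seed = 63)
  lab <- st$violations
  stuck <- lab[lab$kind == "stuck_run", ]
  expect_equal(nrow(stuck), 5)
  rows <- st$records$station_id == st0$meta$station_id[2] &
    st$records$date %in% stuck$date
  expect_equal(length(unique(round(st$records$tmean_c[rows], 2))), 1)

  imp <- lab[lab$kind == "impossible", ]
  row <- st$records$station_id == st0$meta$station_id[3] &
    st$records$date == imp$date
  expect_lt(st$records$tmax_c[row], st$records$tmin_c[row])

  expect_error(sample_stations(tr, 1000), "n_stations")
})

test_that("every planted violation is labelled and nothing else is", {
  fx <- fx_qa()
  lab <- fx$stations$violations
  # one label block per plan entry; short records label each surviving day
  expect_equal(length(unique(paste(lab$station_id, lab$kind))), 40)
  expect_true(all(lab$expected_check %in% c("a", "b", "c", "d")))
})

test_that("model-direction simulation has the promised moments", {
  fx <- fx_model()
  beta <- fx_model_beta()
  sim <- simulate_from_model(fx$design, beta, re_sd = c(0, 0, 0),
                             sigma = 0, seed = 71)
  X <- tagrid:::calibration_model_matrix(fx$design)
  expect_equal(sim$design$ta, as.vector(X %*% beta), tolerance = 1e-12)

  sim2 <- simulate_from_model(fx$design, beta, re_sd = c(2, 0.5, 0.5),
                              sigma = 1, seed = 72)
  resid <- sim2$design$ta - as.vector(X %*% beta)
  expect_gt(sd(resid), 1)  # random effects + residual noise present
})
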