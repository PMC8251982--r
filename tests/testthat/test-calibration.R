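# Design construction, mixed-model fit, and prediction.

test_that("design rows carry the correct time, season, and scaling", {
  fx <- fx_small()
  raw <- build_design(fx$stations$records, fx$stations$meta, fx$lst,
                      fx$region, 2018, "tmean", standardize = FALSE)
  jan1 <- raw[raw$day == 1, ][1, ]
  expect_equal(jan1$sin_time, 0)
  expect_equal(jan1$cos_time, 1)
  dec15 <- raw[format(raw$date, "%m-%d") == "12-15", ][1, ]
  expect_equal(as.character(dec15$season), "cold_dry")
  apr <- raw[format(raw$date, "%m") == "04", ][1, ]
  expect_equal(as.character(apr$season), "warm_dry")
  jul <- raw[format(raw$date, "%m") == "07", ][1, ]
  expect_equal(as.character(jul$season), "rainy")

  std <- build_design(fx$stations$records, fx$stations$meta, fx$lst,
                      fx$region, 2018, "tmean")
  for (v in c("day_lst", "night_lst", "ndvi", "sin_time", "cos_time",
              "elev", "wind")) {
    expect_lt(abs(mean(std[[v]])), 1e-9)
    expect_equal(sd(std[[v]]), 1, tolerance = 1e-9)
  }
  # outcome stays in natural degrees
  expect_equal(std$ta, raw$ta)
  # indicators unscaled
  expect_true(all(std$imputed_day %in% c(0, 1)))
})

test_that("manual prediction reproduces the training-set fitted values", {
  fx <- fx_small()
  qa <- run_qa(fx$stations$records, fx$stations$meta)
  fit <- ta_calibrate(qa$records, fx$stations$meta, fx$lst, fx$region,
                      2018, "tmean")
  raw <- build_design(qa$records, fx$stations$meta, fx$lst, fx$region,
                      2018, "tmean", standardize = FALSE)
  p <- predict(fit, raw)
  expect_equal(as.vector(p), as.vector(fitted(fit)), tolerance = 1e-8)
})

test_that("the linear predictor matches a hand-computed toy case", {
  fx <- fx_small()
  qa <- run_qa(fx$stations$records, fx$stations$meta)
  fit <- ta_calibrate(qa$records, fx$stations$meta, fx$lst, fx$region,
                      2018, "tmean")
  beta <- coef(fit)
  sc <- fit$scaling

  nd <- data.frame(day_lst = c(20, 25, 15), night_lst = c(5, 8, 2),
                   imputed_day = c(0, 1, 0), imputed_night = c(0, 0, 1),
                   ndvi = c(0.3, 0.5, 0.1), sin_time = sin(2 * pi * 0.3),
                   cos_time = cos(2 * pi * 0.3), elev = c(2200, 2600, 3100),
                   wind = c(3, 4, 2),
                   season = factor("warm_dry", c("cold_dry", "warm_dry", "rainy")),
                   day = 110L)
  p <- predict(fit, nd)

  z <- function(v, x) (x - sc$center[[v]]) / sc$scale[[v]]
  u <- fit$ranef_day[fit$ranef_day$day == 110, ]
  for (i in 1:3) {
    zs <- c(day_lst = z("day_lst", nd$day_lst[i]),
            night_lst = z("night_lst", nd$night_lst[i]))
    eta <- beta[["(Intercept)"]] +
      beta[["day_lst"]] * zs["day_lst"] +
      beta[["night_lst"]] * zs["night_lst"] +
      beta[["imputed_day"]] * nd$imputed_day[i] +
      beta[["imputed_night"]] * nd$imputed_night[i] +
      beta[["ndvi"]] * z("ndvi", nd$ndvi[i]) +
      beta[["sin_time"]] * z("sin_time", nd$sin_time[i]) +
      beta[["cos_time"]] * z("cos_time", nd$cos_time[i]) +
      beta[["elev"]] * z("elev", nd$elev[i]) +
      beta[["wind"]] * z("wind", nd$wind[i]) +
      beta[["seasonwarm_dry"]] +
      beta[["day_lst:seasonwarm_dry"]] * zs["day_lst"] +
      beta[["night_lst:seasonwarm_dry"]] * zs["night_lst"] +
      u$intercept + u$day_lst * zs["day_lst"] + u$night_lst * zs["night_lst"]
    expect_equal(unname(p[i]), unname(eta), tolerance = 1e-9)
  }
})

test_that("days absent from training fall back to the fixed part", {
  fx <- fx_small()
  qa <- run_qa(fx$stations$records, fx$stations$meta)
  # train on the first half of the year only
  half <- qa$records[as.integer(format(qa$records$date, "%j")) <= 180, ]
  fit <- ta_calibrate(half, fx$stations$meta, fx$lst, fx$region, 2018, "tmean")
  nd <- data.frame(day_lst = 20, night_lst = 5, imputed_day = 0,
                   imputed_night = 0, ndvi = 0.3,
                   sin_time = sin(2 * pi * 0.6), cos_time = cos(2 * pi * 0.6),
                   elev = 2500, wind = 3,
                   season = factor("rainy", c("cold_dry", "warm_dry", "rainy")),
                   day = 220L)
  p <- predict(fit, nd)
  expect_true(attr(p, "new_day"))
  # same covariates on a trained day include that day's random effects
  nd2 <- nd
  nd2$day <- 100L
  p2 <- predict(fit, nd2)
  expect_false(attr(p2, "new_day"))
})

test_that("shifting all elevations leaves predictions unchanged", {
  fx <- fx_small()
  qa <- run_qa(fx$stations$records, fx$stations$meta)
  region2 <- fx$region
  region2$cells$elev_m <- region2$cells$elev_m + 500
  meta2 <- fx$stations$meta
  meta2$elev_m <- meta2$elev_m + 500

  fit1 <- ta_calibrate(qa$records, fx$stations$meta, fx$lst, fx$region,
                       2018, "tmean")
  fit2 <- ta_calibrate(qa$records, meta2, fx$lst, region2, 2018, "tmean")
  expect_equal(as.vector(fitted(fit1)), as.vector(fitted(fit2)),
               tolerance = 1e-6)
})

test_that("fit object exposes the standard accessors", {
  fx <- fx_small()
  qa <- run_qa(fx$stations$records, fx$stations$meta)
  fit <- ta_calibrate(qa$records, fx$stations$meta, fx$lst, fx$region,
                      2018, "tmean")
  expect_s3_class(fit, "ta_fit")
  expect_named(coef(fit))
  expect_equal(length(residuals(fit)), fit$n_obs)
  expect_output(print(fit), "ta_fit")
  expect_output(print(summary(fit)), "Fixed effects")
  # per-day random intercepts centre near zero (shrinkage)
  re <- fit$ranef_day$intercept
  expect_lt(abs(mean(re)), 0.1 * sd(re))
  # random-slope switch produces an intercept-only structure
  small <- qa$records[as.integer(format(qa$records$date, "%j")) <= 40, ]
  fit0 <- ta_calibrate(small, fx$stations$meta, fx$lst, fx$region, 2018,
                       "tmean", random_slopes = FALSE)
  expect_match(fit0$re_structure, "intercept")
  expect_true(all(fit0$ranef_day$day_lst == 0))
})
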