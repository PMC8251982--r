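# Folds, metrics, and cross-validation machinery.

test_that("fold assignment is balanced, seeded, and prediction-area only", {
  st <- sprintf("S%02d", 1:40)
  f <- make_folds(st, k = 10, seed = 5)
  expect_equal(unname(table(f)), rep(4L, 10), ignore_attr = TRUE)
  expect_identical(f, make_folds(st, k = 10, seed = 5))
  expect_false(identical(f, make_folds(st, k = 10, seed = 6)))
  expect_warning(f2 <- make_folds(st[1:6], k = 10, seed = 5), "reducing k")
  expect_equal(max(f2), 6)
})

test_that("basic metrics match a brute-force oracle and edge cases", {
  set.seed(31)
  y <- rnorm(300, 15, 4)
  p <- y + rnorm(300, 0, 1.2)
  m <- basic_metrics(y, p)
  expect_equal(m$rmse, sqrt(sum((y - p)^2) / 300), tolerance = 1e-12)
  expect_equal(m$sd, sqrt(sum((y - mean(y))^2) / 299), tolerance = 1e-12)
  expect_equal(m$improvement, m$sd - m$rmse, tolerance = 1e-12)
  expect_equal(m$r2, 1 - mean((y - p)^2) / var(y), tolerance = 1e-12)

  mp <- basic_metrics(y, y)
  expect_equal(mp$rmse, 0)
  expect_equal(mp$r2, 1)

  mnull <- basic_metrics(y, rep(mean(y), 300))
  expect_equal(mnull$r2, 1 - 299 / 300, tolerance = 1e-12)  # ~0, sample variance

  expect_true(is.na(basic_metrics(1, 1)$rmse))
})

test_that("spatial weighting gives each day-quarter-degree group weight one", {
  set.seed(32)
  n <- 120
  y <- rnorm(n, 20, 3)
  p <- y + rnorm(n, 0, 1)
  lon <- runif(n, -100, -98)
  lat <- runif(n, 18, 20)
  day <- sample(as.Date("2018-06-01") + 0:9, n, replace = TRUE)

  w <- weighted_metrics(y, p, lon, lat, day)
  # brute-force oracle
  g <- paste(day, floor(lon / 0.25), floor(lat / 0.25))
  wt <- 1 / table(g)[g]
  wt <- as.numeric(wt)
  wm <- sum(wt * y) / sum(wt)
  expect_equal(w$rmse_weighted, sqrt(sum(wt * (y - p)^2) / sum(wt)),
               tolerance = 1e-12)
  expect_equal(w$sd_weighted, sqrt(sum(wt * (y - wm)^2) / sum(wt)),
               tolerance = 1e-12)

  # one observation per group -> weighted equals unweighted (population SD)
  y1 <- rnorm(50); p1 <- y1 + rnorm(50)
  w1 <- weighted_metrics(y1, p1, -100 + (0:49) * 0.26,
                         rep(19.1, 50), rep(as.Date("2018-01-01"), 50))
  expect_equal(w1$rmse_weighted, sqrt(mean((y1 - p1)^2)), tolerance = 1e-12)

  # two observations sharing a group each carry half weight
  w2 <- weighted_metrics(c(10, 20), c(10, 20), c(-99.01, -99.02),
                         c(19.01, 19.02), rep(as.Date("2018-01-01"), 2))
  expect_equal(w2$n_groups, 1)
})

test_that("R2 decomposes into spatial and temporal components", {
  set.seed(33)
  st <- rep(sprintf("S%d", 1:5), each = 40)
  y <- rnorm(200, rep(c(12, 15, 18, 21, 24), each = 40), 2)
  # perfect predictions
  r <- r2_decomposition(y, y, st)
  expect_equal(r$r2_spatial, 1)
  expect_equal(r$r2_temporal, 1)

  # station-constant offsets: temporal perfect, spatial = cor of means
  off <- rep(c(0, 1, -2, 3, 0.5), each = 40)
  p <- y + off
  r2 <- r2_decomposition(y, p, st)
  expect_equal(r2$r2_temporal, 1, tolerance = 1e-12)
  My <- tapply(y, st, mean)
  Mp <- tapply(p, st, mean)
  expect_equal(r2$r2_spatial, cor(My, Mp)^2, tolerance = 1e-12)

  # single station: spatial undefined, temporal defined
  r1 <- r2_decomposition(y[1:40], p[1:40], st[1:40])
  expect_true(is.na(r1$r2_spatial))
  expect_false(is.na(r1$r2_temporal))
})

test_that("cross-validation covers each prediction-area observation once", {
  cv <- fx_model_cv()
  obs <- cv$obs
  key <- paste(obs$station_id, obs$date)
  expect_false(any(duplicated(key)))
  # every scored station is a prediction-area station in exactly one fold
  sf <- unique(obs[, c("station_id", "fold")])
  expect_false(any(duplicated(sf$station_id)))
  expect_equal(sort(unique(obs$fold)), 1:10)
})

test_that("forcing predictions equal to observations zeroes the error", {
  cv <- fx_model_cv()
  fake <- cv$obs
  fake$p <- fake$y
  expect_equal(evaluate_cv(fake)$rmse, 0)
  expect_equal(evaluate_cv(fake)$r2, 1)
})

test_that("the crowdsourced-network ablation runs and reports both CVs", {
  fx <- fx_small()
  qa <- run_qa(fx$stations$records, fx$stations$meta)
  ab <- wu_ablation(qa$records, fx$stations$meta, fx$lst, fx$region,
                    2018, "tmean", k = 3, seed = 61)
  expect_true(is.finite(ab$diff))
  expect_equal(ab$diff, ab$rmse_nwu - ab$rmse_wu, tolerance = 1e-12)
  # tests restricted to non-crowdsourced stations in both arms
  crowd <- fx$stations$meta$station_id[fx$stations$meta$crowdsourced]
  expect_false(any(ab$cv_nwu$obs$station_id %in% crowd))
  expect_false(any(ab$cv_wu$obs$station_id %in% crowd))

  # no crowdsourced stations -> ablation undefined
  meta0 <- fx$stations$meta
  meta0$crowdsourced <- FALSE
  expect_warning(r <- wu_ablation(qa$records, meta0, fx$lst, fx$region,
                                  2018, "tmean", k = 3, seed = 61),
                 "undefined")
  expect_null(r)
})

test_that("the learning curve is reproducible and labels its rounds", {
  fx <- fx_model()
  sim <- fx_model_sim()
  rec <- fx_records_from_design(fx, sim$design)
  cv <- fx_model_cv()
  lc1 <- learning_curve(rec, fx$stations$meta, fx$lst, fx$region, 2018,
                        "tmean", stations_per_round = c(6, 12),
                        obs_per_round = c(800, 1600), replicates = 1,
                        seed = 71, base_cv = cv)
  lc2 <- learning_curve(rec, fx$stations$meta, fx$lst, fx$region, 2018,
                        "tmean", stations_per_round = c(6, 12),
                        obs_per_round = c(800, 1600), replicates = 1,
                        seed = 71, base_cv = cv)
  expect_identical(lc1, lc2)
  expect_equal(unique(lc1$round), 1:2)
  expect_equal(unique(lc1$n_obs), c(800, 1600))
  # an oversized round is skipped with a warning
  expect_warning(
    lc3 <- learning_curve(rec, fx$stations$meta, fx$lst, fx$region, 2018,
                          "tmean", stations_per_round = 500,
                          obs_per_round = 1000, replicates = 1,
                          seed = 72, base_cv = cv),
    "skipped")
  expect_null(lc3)
})
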