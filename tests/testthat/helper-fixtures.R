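# Shared synthetic fixtures, built once per test run and cached.

.fx_cache <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (!exists(name, envir = .fx_cache)) {
    assign(name, builder(), envir = .fx_cache)
  }
  get(name, envir = .fx_cache)
}

# Small clean scenario: 15x15 region, 25 stations, one year, merged and
# gap-filled LST. No planted violations.
fx_small <- function() {
  fx_get("small", function() {
    region <- simulate_region(15, 15, seed = 101)
    truth <- simulate_truth(region, 2018, seed = 102)
    stations <- sample_stations(truth, 25, seed = 103)
    sat1 <- simulate_lst(truth, missing_fraction = 0.3, seed = 104)
    sat2 <- simulate_lst(truth, missing_fraction = 0.3, seed = 105)
    lst <- gapfill_lst(merge_satellites(sat1, sat2))
    list(region = region, truth = truth, stations = stations, lst = lst,
         year = 2018)
  })
}

# Model-direction scenario: design built from a 50-station year, response
# re-simulated from the calibration equation with known coefficients.
fx_model_beta <- function() {
  c("(Intercept)" = 16, day_lst = 2.2, night_lst = 2.8,
    imputed_day = -0.2, imputed_night = -0.15, ndvi = -0.4,
    sin_time = -0.6, cos_time = -2.5, elev = -2, wind = 0.2,
    seasonwarm_dry = 0.8, seasonrainy = 0.5,
    "day_lst:seasonwarm_dry" = 0.3, "day_lst:seasonrainy" = -0.4,
    "night_lst:seasonwarm_dry" = 0.2, "night_lst:seasonrainy" = -0.3)
}

fx_model <- function() {
  fx_get("model", function() {
    region <- simulate_region(20, 20, seed = 201)
    truth <- simulate_truth(region, 2018, seed = 202)
    stations <- sample_stations(truth, 50, seed = 203, wind_missing = 0)
    sat1 <- simulate_lst(truth, missing_fraction = 0.3, seed = 204)
    sat2 <- simulate_lst(truth, missing_fraction = 0.3, seed = 205)
    lst <- gapfill_lst(merge_satellites(sat1, sat2))
    design <- build_design(stations$records, stations$meta, lst, region,
                           2018, "tmean")
    list(region = region, truth = truth, stations = stations, lst = lst,
         design = design, year = 2018)
  })
}

# Push a simulated response back into the station records so the
# cross-validation operates on data generated from the calibration
# equation itself.
fx_records_from_design <- function(fx, design_with_y) {
  rec <- fx$stations$records
  rec$tmean_c <- NA_real_
  key_r <- paste(rec$station_id, rec$date)
  key_d <- paste(design_with_y$station_id, design_with_y$date)
  rec$tmean_c[match(key_d, key_r)] <- design_with_y$ta
  rec
}

# One response realisation from the calibration equation at residual SD 1.
fx_model_sim <- function() {
  fx_get("model_sim", function() {
    fx <- fx_model()
    simulate_from_model(fx$design, fx_model_beta(),
                        re_sd = c(2, 0.5, 0.5), sigma = 1, seed = 777)
  })
}

# Full 10-fold station-holdout CV on the model-direction records.
fx_model_cv <- function() {
  fx_get("model_cv", function() {
    fx <- fx_model()
    rec <- fx_records_from_design(fx, fx_model_sim()$design)
    cross_validate(rec, fx$stations$meta, fx$lst, fx$region, 2018,
                   "tmean", k = 10, seed = 555)
  })
}

# QA-fidelity scenario: 50 stations, one year, 40 planted violations
# spanning all four checks (seed chosen so the clean remainder triggers no
# accidental a-c flags).
fx_qa <- function() {
  fx_get("qa", function() {
    region <- simulate_region(20, 20, seed = 301)
    truth <- simulate_truth(region, 2018, seed = 302)
    # spikes go on stations the buddy check can actually evaluate
    meta0 <- sample_stations(truth, 50, seed = 305)$meta
    # margin: spikes stay evaluable even if all short-record stations
# (8 of the 40 planted violations) were among their neighbours
pool <- which(eligible_neighbor_counts(meta0) >= 3 + 8)
    plan <- plant_violation_plan(50, 365, n = 40, seed = 303,
                                 spike_pool = pool)
    stations <- sample_stations(truth, 50, violations = plan, seed = 305)
    list(region = region, truth = truth, stations = stations, plan = plan,
         year = 2018)
  })
}
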