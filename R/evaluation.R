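# Station-holdout cross-validation and the model-performance metric suite.

#' Split prediction-area stations into cross-validation folds
#'
#' Folds are as equal-sized as possible and deterministic under the seed.
#' Stations outside the prediction area receive no fold (they always
#' train).
#'
#' @param stations Character vector of prediction-area station ids.
#' @param k Number of folds (reduced with a warning if fewer stations).
#' @param seed Integer seed.
#' @return Named integer vector: fold per station.
#' @export
make_folds <- function(stations, k = 10, seed = NULL) {
  n <- length(stations)
  if (n < k) {
    warning(sprintf("only %d stations for %d folds; reducing k to %d", n, k, n))
    k <- n
  }
  with_seed(seed, {
    shuffled <- sample(stations)
    f <- rep(seq_len(k), length.out = n)
    stats::setNames(f[match(stations, shuffled)], stations)
  })
}

#' Station-holdout cross-validation of the calibration model
#'
#' For each fold, trains on the stations of the other folds plus all
#' stations outside the prediction area, and predicts the held-out fold's
#' observations. Held-out stations' mean wind speed is always imputed from
#' training stations, as if the test stations never reported wind, so no
#' test-station information enters training.
#'
#' @param records QA-cleaned station-day records.
#' @param station_meta Station table (with `cell_id`,
#'   `in_prediction_area`, `crowdsourced`).
#' @param lst Gap-filled `lst_stack`.
#' @param grid `master_grid`.
#' @param year Calendar year.
#' @param outcome `"tmin"`, `"tmean"`, or `"tmax"`.
#' @param k Number of folds.
#' @param seed Fold seed (ignored when `folds` supplied).
#' @param folds Optional precomputed station->fold map.
#' @param exclude_train_stations Station ids never used in training (e.g.
#'   the crowdsourced network, for the ablation).
#' @param test_stations Optional restriction of which stations are scored.
#' @param random_slopes Passed to [fit_ta_model()].
#' @return A `ta_cv` object: data.frame `obs` (station_id, date, fold, y,
#'   p, lon, lat) plus metadata.
#' @export
cross_validate <- function(records, station_meta, lst, grid, year,
                           outcome = c("tmean", "tmin", "tmax"),
                           k = 10, seed = NULL, folds = NULL,
                           exclude_train_stations = NULL,
                           test_stations = NULL,
                           random_slopes = TRUE) {
  outcome <- match.arg(outcome)
  pa <- station_meta$station_id[station_meta$in_prediction_area]
  folds <- folds %||% make_folds(pa, k, seed)
  out <- list()
  for (f in sort(unique(folds))) {
    test_st <- names(folds)[folds == f]
    if (!is.null(test_stations)) test_st <- intersect(test_st, test_stations)
    test_rec <- records[records$station_id %in% test_st, , drop = FALSE]
    test_rec <- test_rec[!is.na(test_rec[[paste0(outcome, "_c")]]), , drop = FALSE]
    if (nrow(test_rec) == 0) {
      warning("fold ", f, " has no test observations; skipped")
      next
    }
    train_st <- setdiff(station_meta$station_id,
                        union(names(folds)[folds == f], exclude_train_stations))
    train_rec <- records[records$station_id %in% train_st, , drop = FALSE]

    fit <- ta_calibrate(train_rec, station_meta, lst, grid, year, outcome,
                        random_slopes = random_slopes)
    # held-out wind: donor-imputed from training stations at all times
    test_rec$wind_ms <- NA_real_
    test_rec <- fill_wind(test_rec, station_meta, donor_records = train_rec,
                          force_all = TRUE)
    nd <- build_design(test_rec, station_meta, lst, grid, year, outcome,
                       standardize = FALSE)
    p <- predict(fit, nd)
    mi <- match(nd$station_id, station_meta$station_id)
    out[[length(out) + 1]] <- data.frame(
      station_id = nd$station_id, date = nd$date, fold = f,
      y = nd$ta, p = as.vector(p),
      lon = station_meta$lon[mi], lat = station_meta$lat[mi],
      wind_used = nd$wind)  # donor-imputed held-out wind, for audit
  }
  obs <- do.call(rbind, out)
  obs <- obs[!is.na(obs$p), , drop = FALSE]
  rownames(obs) <- NULL
  structure(list(obs = obs, folds = folds, year = year, outcome = outcome),
            class = "ta_cv")
}

#' @export
print.ta_cv <- function(x, ...) {
  m <- basic_metrics(x$obs$y, x$obs$p)
  cat(sprintf("ta_cv: %s Ta %s, %d held-out observations, %d folds\n",
              x$outcome, x$year, nrow(x$obs), length(unique(x$obs$fold))))
  cat(sprintf("  RMSE %.3f K, SD %.3f K, R2 %.3f\n", m$rmse, m$sd, m$r2))
  invisible(x)
}

#' Basic prediction metrics
#'
#' `RMSE = sqrt(mean((y - p)^2))`; `SD` = sample SD of the observations;
#' `improvement = SD - RMSE`; `R2 = 1 - mean((y - p)^2) / Var(y)` with the
#' sample (n-1) variance.
#'
#' @param y Observations. @param p Predictions.
#' @return List `sd`, `rmse`, `improvement`, `r2`, `n` (all `NA` when
#'   `n < 2`).
#' @export
basic_metrics <- function(y, p) {
  ok <- !is.na(y) & !is.na(p)
  y <- y[ok]; p <- p[ok]
  n <- length(y)
  if (n < 2) {
    return(list(sd = NA_real_, rmse = NA_real_, improvement = NA_real_,
                r2 = NA_real_, n = n))
  }
  mse <- mean((y - p)^2)
  s <- stats::sd(y)
  list(sd = s, rmse = sqrt(mse), improvement = s - sqrt(mse),
       r2 = 1 - mse / stats::var(y), n = n)
}

#' Spatially weighted prediction metrics
#'
#' Each (day, quarter-degree longitude bin, quarter-degree latitude bin)
#' group with at least one observation gets total weight 1, shared equally
#' by its observations; bins are anchored at integer degrees.
#'
#' @param y,p Observations and predictions.
#' @param lon,lat Station coordinates (degrees).
#' @param day Day identifier (e.g. `Date`).
#' @return List `sd_weighted`, `rmse_weighted`, `n_groups`.
#' @export
weighted_metrics <- function(y, p, lon, lat, day) {
  ok <- !is.na(y) & !is.na(p)
  y <- y[ok]; p <- p[ok]; lon <- lon[ok]; lat <- lat[ok]; day <- day[ok]
  g <- paste(day, floor(lon / 0.25), floor(lat / 0.25))
  size <- table(g)
  w <- 1 / as.vector(size[g])
  wm <- sum(w * y) / sum(w)
  list(sd_weighted = sqrt(sum(w * (y - wm)^2) / sum(w)),
       rmse_weighted = sqrt(sum(w * (y - p)^2) / sum(w)),
       n_groups = length(size))
}

#' Spatial and temporal R-squared decomposition
#'
#' With per-station annual means `M_y` and `M_p`: the spatial R2 is the
#' squared correlation between `M_y` and `M_p` (sample size = number of
#' stations); the temporal R2 is the squared correlation between
#' `y - M_y` and `p - M_p`.
#'
#' @param y,p Observations and predictions.
#' @param station_ids Station of each observation.
#' @return List `r2_spatial` (NA with < 2 stations), `r2_temporal`,
#'   `n_stations`.
#' @export
r2_decomposition <- function(y, p, station_ids) {
  ok <- !is.na(y) & !is.na(p)
  y <- y[ok]; p <- p[ok]; station_ids <- station_ids[ok]
  My <- tapply(y, station_ids, mean)
  Mp <- tapply(p, station_ids, mean)
  ns <- length(My)
  r2s <- if (ns >= 2 && stats::sd(My) > 0 && stats::sd(Mp) > 0) {
    stats::cor(My, Mp)^2
  } else NA_real_
  yd <- y - My[as.character(station_ids)]
  pd <- p - Mp[as.character(station_ids)]
  r2t <- if (stats::sd(yd) > 0 && stats::sd(pd) > 0) stats::cor(yd, pd)^2 else NA_real_
  list(r2_spatial = r2s, r2_temporal = r2t, n_stations = ns)
}

#' Full metric suite for a cross-validation result
#'
#' @param cv A `ta_cv` (or a data.frame with `y`, `p`, `lon`, `lat`,
#'   `date`, `station_id`).
#' @return One-row data.frame with n, stations, SD, RMSE, improvement, R2,
#'   weighted SD/RMSE, spatial and temporal R2.
#' @export
evaluate_cv <- function(cv) {
  obs <- if (inherits(cv, "ta_cv")) cv$obs else cv
  b <- basic_metrics(obs$y, obs$p)
  w <- weighted_metrics(obs$y, obs$p, obs$lon, obs$lat, obs$date)
  r <- r2_decomposition(obs$y, obs$p, obs$station_id)
  data.frame(n = b$n, stations = r$n_stations,
             sd = b$sd, rmse = b$rmse, improvement = b$improvement,
             r2 = b$r2, sd_weighted = w$sd_weighted,
             rmse_weighted = w$rmse_weighted,
             r2_spatial = r$r2_spatial, r2_temporal = r$r2_temporal)
}

#' Crowdsourced-network training ablation
#'
#' Both cross-validations test only on non-crowdsourced prediction-area
#' stations. `RMSE_NWU` trains without the crowdsourced network;
#' `RMSE_WU` with it. Returns `RMSE_NWU - RMSE_WU` on the spatially
#' weighted RMSE (positive = crowdsourced data helped); the unweighted
#' difference is also reported.
#'
#' @inheritParams cross_validate
#' @return List `diff`, `diff_unweighted`, `rmse_nwu`, `rmse_wu`, and both
#'   `ta_cv` objects; `NULL` with a warning when no crowdsourced stations
#'   exist.
#' @export
wu_ablation <- function(records, station_meta, lst, grid, year,
                        outcome = c("tmean", "tmin", "tmax"),
                        k = 10, seed = NULL) {
  outcome <- match.arg(outcome)
  crowd <- station_meta$station_id[station_meta$crowdsourced]
  if (length(crowd) == 0) {
    warning("no crowdsourced stations present; ablation undefined")
    return(NULL)
  }
  ref_pa <- station_meta$station_id[station_meta$in_prediction_area &
                                      !station_meta$crowdsourced]
  folds <- make_folds(ref_pa, k, seed)
  cv_nwu <- cross_validate(records, station_meta, lst, grid, year, outcome,
                           folds = folds, exclude_train_stations = crowd)
  cv_wu <- cross_validate(records, station_meta, lst, grid, year, outcome,
                          folds = folds)
  m_nwu <- evaluate_cv(cv_nwu)
  m_wu <- evaluate_cv(cv_wu)
  list(diff = m_nwu$rmse_weighted - m_wu$rmse_weighted,
       diff_unweighted = m_nwu$rmse - m_wu$rmse,
       rmse_nwu = m_nwu$rmse_weighted, rmse_wu = m_wu$rmse_weighted,
       cv_nwu = cv_nwu, cv_wu = cv_wu)
}

#' Learning curve: accuracy as a function of training-set size
#'
#' Two test folds are fixed: the folds whose per-fold unweighted CV RMSE is
#' closest to the overall CV RMSE. In round `r`, `stations_per_round[r]`
#' stations are sampled from the remaining (non-test) prediction-area
#' pool, `obs_per_round[r]` of their observations are sampled without
#' replacement, the model is trained on them, and the fixed test folds are
#' scored. Defaults follow the full-scale protocol (10r stations, 2,500r
#' observations, 7 rounds, 100 replicates); pass smaller vectors for desk
#' scale.
#'
#' @inheritParams cross_validate
#' @param stations_per_round,obs_per_round Per-round training sizes.
#' @param replicates Replicates per round.
#' @param base_cv Optional precomputed full `ta_cv` used to pick the test
#'   folds.
#' @return data.frame (round, n_stations, n_obs, replicate, rmse); rounds
#'   whose requirement exceeds the pool are skipped with a warning.
#' @export
learning_curve <- function(records, station_meta, lst, grid, year,
                           outcome = c("tmean", "tmin", "tmax"),
                           stations_per_round = 10 * (1:7),
                           obs_per_round = 2500 * (1:7),
                           replicates = 100, k = 10, seed = NULL,
                           base_cv = NULL, random_slopes = TRUE) {
  outcome <- match.arg(outcome)
  cv <- base_cv %||% cross_validate(records, station_meta, lst, grid, year,
                                    outcome, k = k,
                                    seed = child_seed(seed, "lc_base"),
                                    random_slopes = random_slopes)
  overall <- basic_metrics(cv$obs$y, cv$obs$p)$rmse
  fold_rmse <- tapply(seq_len(nrow(cv$obs)), cv$obs$fold, function(i) {
    basic_metrics(cv$obs$y[i], cv$obs$p[i])$rmse
  })
  test_folds <- as.integer(names(sort(abs(fold_rmse - overall))[1:2]))
  test_st <- names(cv$folds)[cv$folds %in% test_folds]
  pool <- setdiff(names(cv$folds), test_st)
  ycol <- paste0(outcome, "_c")
  test_rec <- records[records$station_id %in% test_st &
                        !is.na(records[[ycol]]), , drop = FALSE]
  pool_rec <- records[records$station_id %in% pool, , drop = FALSE]

  res <- list()
  with_seed(child_seed(seed, "lc_rounds"), {
    for (r in seq_along(stations_per_round)) {
      n_st <- stations_per_round[r]
      n_ob <- obs_per_round[r]
      if (n_st > length(pool)) {
        warning(sprintf("round %d needs %d stations but pool has %d; skipped",
                        r, n_st, length(pool)))
        next
      }
      for (rep_i in seq_len(replicates)) {
        st <- sample(pool, n_st)
        cand <- which(pool_rec$station_id %in% st & !is.na(pool_rec[[ycol]]))
        if (length(cand) < n_ob) {
          warning(sprintf("round %d replicate %d: only %d observations available (%d requested); skipped",
                          r, rep_i, length(cand), n_ob))
          next
        }
        rows <- sample(cand, n_ob)
        train_rec <- pool_rec[rows, , drop = FALSE]
        fit <- ta_calibrate(train_rec, station_meta, lst, grid, year, outcome,
                            random_slopes = random_slopes)
        tr <- test_rec
        tr$wind_ms <- NA_real_
        # wind donors: the selected stations' full series (imputation is
        # preprocessing; sampling applies to the outcome observations)
        donors <- pool_rec[pool_rec$station_id %in% st, , drop = FALSE]
        tr <- fill_wind(tr, station_meta, donor_records = donors,
                        force_all = TRUE)
        nd <- build_design(tr, station_meta, lst, grid, year, outcome,
                           standardize = FALSE)
        p <- predict(fit, nd)
        res[[length(res) + 1]] <- data.frame(
          round = r, n_stations = n_st, n_obs = n_ob, replicate = rep_i,
          rmse = sqrt(mean((nd$ta - p)^2, na.rm = TRUE)))
      }
    }
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(NULL)
  attr(out, "test_folds") <- test_folds
  attr(out, "test_stations") <- test_st
  out
}
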