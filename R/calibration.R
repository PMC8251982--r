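# Per-year, per-outcome calibration of daily air temperature on satellite
# LST: linear mixed model with day-specific random intercepts and
# day-varying LST slopes.

.CAL_FIXED_FORMULA <- ta ~ day_lst + night_lst + imputed_day + imputed_night +
  ndvi + sin_time + cos_time + elev + wind + season +
  day_lst:season + night_lst:season

.CONTINUOUS_COVARIATES <- c("day_lst", "night_lst", "ndvi", "sin_time",
                            "cos_time", "elev", "wind")

#' Build the calibration design table
#'
#' Joins QA-cleaned station-days with the (gap-filled) LST stack at each
#' station's grid cell and the static covariates, producing one row per
#' station-day with an outcome value and an LST value. The time covariate
#' is `(day of year - 1) / (days in year - 1)`; the season factor is
#' cold-dry (Nov-Feb), warm-dry (Mar-Apr), rainy (May-Oct). All continuous
#' covariates are centred and scaled (by training mean/SD); indicator and
#' season columns are left unscaled; the outcome stays in degC.
#'
#' @param records Cleaned station-day data.frame; missing wind is imputed
#'   from the nearest station (these records as donors).
#' @param station_meta Station table with `cell_id` (see
#'   [assign_station_cells()]).
#' @param lst A gap-filled `lst_stack` for the year.
#' @param grid The `master_grid` (provides elevation and monthly NDVI).
#' @param year Calendar year.
#' @param outcome One of `"tmin"`, `"tmean"`, `"tmax"`.
#' @param standardize Centre/scale continuous covariates (`TRUE` for
#'   training; prediction paths pass raw values and apply the stored fit
#'   scaling instead).
#' @param scaling Optional stored scaling (list with `center`, `scale`) to
#'   apply instead of computing fresh constants.
#' @return Design data.frame with attribute `"scaling"`.
#' @export
build_design <- function(records, station_meta, lst, grid, year,
                         outcome = c("tmean", "tmin", "tmax"),
                         standardize = TRUE, scaling = NULL) {
  outcome <- match.arg(outcome)
  ycol <- paste0(outcome, "_c")
  records <- records[as.integer(format(records$date, "%Y")) == year, , drop = FALSE]
  records <- records[!is.na(records[[ycol]]), , drop = FALSE]
  if (nrow(records) == 0) stop("no records with the requested outcome in ", year)
  if (anyNA(records$wind_ms)) {
    records <- fill_wind(records, station_meta)
  }

  mi <- match(records$station_id, station_meta$station_id)
  cell <- station_meta$cell_id[mi]
  gi <- match(cell, grid$cells$cell_id)
  di <- match(records$date, lst$dates)
  if (anyNA(gi) || anyNA(di)) stop("records reference cells or dates outside the grid/LST stack")

  day_lst <- lst$day[cbind(gi, di)]
  night_lst <- lst$night[cbind(gi, di)]
  ok <- !is.na(day_lst) & !is.na(night_lst)
  if (!any(ok)) stop("empty intersection of station records and LST coverage")

  nd <- days_in_year(year)
  doy <- as.integer(format(records$date, "%j"))
  tt <- (doy - 1) / (nd - 1)
  month <- as.integer(format(records$date, "%m"))

  design <- data.frame(
    ta = records[[ycol]],
    day_lst = day_lst, night_lst = night_lst,
    imputed_day = lst$imputed_day[cbind(gi, di)],
    imputed_night = lst$imputed_night[cbind(gi, di)],
    ndvi = grid$ndvi[cbind(gi, month)],
    sin_time = sin(2 * pi * tt), cos_time = cos(2 * pi * tt),
    elev = grid$cells$elev_m[gi],
    wind = records$wind_ms,
    season = season_of_month(month),
    day = doy,
    station_id = records$station_id,
    cell_id = cell,
    date = records$date
  )[ok, , drop = FALSE]
  rownames(design) <- NULL

  if (standardize || !is.null(scaling)) {
    if (is.null(scaling)) {
      center <- vapply(design[.CONTINUOUS_COVARIATES], mean, numeric(1))
      scale <- vapply(design[.CONTINUOUS_COVARIATES], stats::sd, numeric(1))
      scale[scale == 0 | is.na(scale)] <- 1  # constant column: centre only
      scaling <- list(center = center, scale = scale)
    }
    for (v in .CONTINUOUS_COVARIATES) {
      design[[v]] <- (design[[v]] - scaling$center[[v]]) / scaling$scale[[v]]
    }
  }
  attr(design, "scaling") <- scaling
  attr(design, "outcome") <- outcome
  attr(design, "year") <- year
  design
}

# fixed-effects model matrix shared by fitting, simulation, and prediction
calibration_model_matrix <- function(design) {
  design$season <- factor(design$season,
                          levels = c("cold_dry", "warm_dry", "rainy"))
  stats::model.matrix(stats::delete.response(stats::terms(.CAL_FIXED_FORMULA)),
                      design)
}

#' Fit the calibration mixed model to a built design
#'
#' REML fit of the fixed part (day/night LST, imputation indicators, NDVI,
#' seasonal sine/cosine, elevation, wind, season, and season-by-LST
#' interactions) with day-level random effects: a random intercept plus
#' random day- and night-LST slopes. The random-effect covariance is
#' unstructured; on non-convergence the fit falls back to independent
#' (diagonal) effects and then to an intercept-only structure, recording
#' the level used. Aliased fixed-effect columns are dropped and reported.
#'
#' @param design From [build_design()] (standardized).
#' @param random_slopes Include the per-day LST random slopes (otherwise
#'   random intercept only).
#' @param max_iter Optimizer iteration cap.
#' @return A `ta_fit` object.
#' @export
fit_ta_model <- function(design, random_slopes = TRUE, max_iter = 200) {
  if (length(unique(design$day)) < 2) stop("need at least 2 distinct days to fit")
  design$day_f <- factor(design$day)
  design$season <- factor(design$season,
                          levels = c("cold_dry", "warm_dry", "rainy"))
  fixed <- if (nlevels(droplevels(design$season)) >= 2) {
    paste("ta ~ day_lst + night_lst + imputed_day + imputed_night +",
          "ndvi + sin_time + cos_time + elev + wind + season +",
          "day_lst:season + night_lst:season")
  } else {
    # single observed season: its contrasts are aliased with the intercept
    paste("ta ~ day_lst + night_lst + imputed_day + imputed_night +",
          "ndvi + sin_time + cos_time + elev + wind")
  }
  res <- c("(1 + day_lst + night_lst | day_f)",
           "(1 + day_lst + night_lst || day_f)",
           "(1 | day_f)")
  structures <- c("unstructured", "diagonal", "intercept")
  if (!random_slopes) { res <- res[3]; structures <- structures[3] }

  ctrl <- lme4::lmerControl(
    optCtrl = list(maxfun = max_iter * 100),
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))
  fit <- NULL; used <- NA_character_; messages <- character()
  for (k in seq_along(res)) {
    form <- stats::as.formula(paste(fixed, "+", res[k]))
    got <- tryCatch({
      warn <- character()
      m <- withCallingHandlers(
        lme4::lmer(form, data = design, REML = TRUE, control = ctrl),
        warning = function(w) {
          warn <<- c(warn, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      conv_fail <- any(grepl("failed to converge", warn))
      list(m = m, warn = warn, conv_fail = conv_fail)
    }, error = function(e) list(m = NULL, warn = conditionMessage(e),
                                conv_fail = TRUE))
    messages <- c(messages, got$warn)
    if (!is.null(got$m) && !got$conv_fail) {
      fit <- got$m; used <- structures[k]; break
    }
    if (!is.null(got$m) && k == length(res)) {
      # last resort: accept the non-converged simplest structure
      fit <- got$m; used <- paste0(structures[k], " (not converged)")
    }
  }
  if (is.null(fit)) {
    stop("calibration model failed to fit: ", paste(messages, collapse = "; "))
  }

  beta <- lme4::fixef(fit)
  Xfull <- calibration_model_matrix(design)
  dropped <- setdiff(colnames(Xfull), names(beta))
  re <- lme4::ranef(fit)$day_f
  ranef_day <- data.frame(day = as.integer(rownames(re)))
  ranef_day$intercept <- re[["(Intercept)"]] %||% rep(0, nrow(re))
  ranef_day$day_lst <- re[["day_lst"]] %||% rep(0, nrow(re))
  ranef_day$night_lst <- re[["night_lst"]] %||% rep(0, nrow(re))

  structure(list(
    coefficients = beta,
    ranef_day = ranef_day,
    scaling = attr(design, "scaling"),
    sigma = stats::sigma(fit),
    varcorr = lme4::VarCorr(fit),
    re_structure = used,
    dropped = dropped,
    messages = messages,
    outcome = attr(design, "outcome") %||% "ta",
    year = attr(design, "year") %||% NA_integer_,
    n_obs = nrow(design),
    n_days = length(unique(design$day)),
    model = fit
  ), class = "ta_fit")
}

#' Calibrate daily air temperature against LST for one year and outcome
#'
#' Convenience wrapper: builds the design with [build_design()] and fits it
#' with [fit_ta_model()].
#'
#' @inheritParams build_design
#' @inheritParams fit_ta_model
#' @return A `ta_fit`.
#' @export
ta_calibrate <- function(records, station_meta, lst, grid, year,
                         outcome = c("tmean", "tmin", "tmax"),
                         random_slopes = TRUE) {
  design <- build_design(records, station_meta, lst, grid, year, outcome)
  fit <- fit_ta_model(design, random_slopes = random_slopes)
  fit$design <- design
  fit
}

#' @export
print.ta_fit <- function(x, ...) {
  cat(sprintf("ta_fit: %s Ta, year %s\n", x$outcome, x$year))
  cat(sprintf("  %d observations, %d training days; residual SD %.3f degC\n",
              x$n_obs, x$n_days, x$sigma))
  cat(sprintf("  random-effect structure: %s\n", x$re_structure))
  if (length(x$dropped)) {
    cat("  dropped aliased fixed columns:", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.ta_fit <- function(object, ...) {
  out <- list(fit = object,
              fixed = stats::coef(summary(object$model)),
              varcorr = object$varcorr)
  class(out) <- "summary.ta_fit"
  out
}

#' @export
print.summary.ta_fit <- function(x, ...) {
  print(x$fit)
  cat("\nFixed effects (standardized covariate scale):\n")
  print(round(x$fixed, 4))
  cat("\nRandom-effect (day) covariance:\n")
  print(x$varcorr)
  invisible(x)
}

#' @export
coef.ta_fit <- function(object, ...) object$coefficients

#' @export
residuals.ta_fit <- function(object, ...) stats::residuals(object$model)

#' @export
fitted.ta_fit <- function(object, ...) stats::fitted(object$model)

#' Predict air temperature for new station-days or cells
#'
#' Computes the linear predictor from the stored fixed coefficients plus
#' the day's random intercept and LST slopes. Covariates in `newdata` are
#' raw (unstandardized); the fit's stored scaling constants are applied.
#' Days absent from training contribute the fixed part only and are
#' flagged in the `"new_day"` attribute.
#'
#' @param object A `ta_fit`.
#' @param newdata data.frame with raw columns `day_lst`, `night_lst`,
#'   `imputed_day`, `imputed_night`, `ndvi`, `sin_time`, `cos_time`,
#'   `elev`, `wind`, `season`, `day`.
#' @param ... Unused.
#' @return Numeric predictions (degC) with a logical `"new_day"`
#'   attribute.
#' @export
predict.ta_fit <- function(object, newdata, ...) {
  sc <- object$scaling
  for (v in .CONTINUOUS_COVARIATES) {
    newdata[[v]] <- (newdata[[v]] - sc$center[[v]]) / sc$scale[[v]]
  }
  X <- calibration_model_matrix(newdata)
  beta <- object$coefficients
  eta <- as.vector(X[, names(beta), drop = FALSE] %*% beta)
  ri <- match(newdata$day, object$ranef_day$day)
  new_day <- is.na(ri)
  add <- ifelse(new_day, 0, object$ranef_day$intercept[ri]) +
    ifelse(new_day, 0, object$ranef_day$day_lst[ri]) * newdata$day_lst +
    ifelse(new_day, 0, object$ranef_day$night_lst[ri]) * newdata$night_lst
  out <- eta + add
  out[is.na(newdata$day_lst) | is.na(newdata$night_lst)] <- NA_real_
  attr(out, "new_day") <- new_day
  out
}

#' Predict a daily temperature surface for all grid cells
#'
#' Builds the prediction design for every retained grid cell on the
#' requested days (LST from the gap-filled stack, NDVI by calendar month,
#' elevation from the grid, wind from the nearest reporting station) and
#' applies [predict.ta_fit()]. Cells whose LST is unavailable even after
#' imputation are `NA`.
#'
#' @param fit A `ta_fit`.
#' @param grid The `master_grid`.
#' @param lst Gap-filled `lst_stack` for the fit's year.
#' @param days Integer days of year to predict (default: all in stack).
#' @param wind_records Station-day records supplying wind donors.
#' @param station_meta Station table for the donors.
#' @return Matrix cells x days (dimnames: cell_id, day), attribute
#'   `"new_day"` marking days absent from training.
#' @export
predict_cells <- function(fit, grid, lst, days = NULL,
                          wind_records, station_meta) {
  if (!is.na(fit$year) && !is.null(lst$year) && fit$year != lst$year) {
    stop("fit year and LST stack year differ")
  }
  nd <- length(lst$dates)
  days <- days %||% seq_len(nd)
  cells <- grid$cells
  n <- nrow(cells)
  doy_all <- as.integer(format(lst$dates, "%j"))
  month_all <- as.integer(format(lst$dates, "%m"))
  ndays_year <- days_in_year(lst$year)
  gi <- match(cells$cell_id, grid$cells$cell_id)

  # nearest reporting station per day supplies the wind covariate
  sm <- station_meta
  Wm <- matrix(NA_real_, nrow(sm), nd)
  dsi <- match(wind_records$station_id, sm$station_id)
  ddi <- match(wind_records$date, lst$dates)
  okw <- !is.na(wind_records$wind_ms) & !is.na(dsi) & !is.na(ddi)
  Wm[cbind(dsi[okw], ddi[okw])] <- wind_records$wind_ms[okw]
  Dcs <- outer(seq_len(n), seq_len(nrow(sm)), function(i, j) {
    dist_km(cells$lon[i], cells$lat[i], sm$lon[j], sm$lat[j])
  })

  out <- matrix(NA_real_, n, length(days),
                dimnames = list(cells$cell_id, days))
  new_day_flag <- logical(length(days))
  for (k in seq_along(days)) {
    j <- which(doy_all == days[k])[1]
    if (is.na(j)) stop("day ", days[k], " not in the LST stack")
    has_wind <- which(!is.na(Wm[, j]))
    jj <- j
    while (length(has_wind) == 0 && jj > 1) {  # same back-search as stations
      jj <- jj - 1
      has_wind <- which(!is.na(Wm[, jj]))
    }
    if (length(has_wind) == 0) stop("no wind donor anywhere on or before day ", days[k])
    nearest <- has_wind[apply(Dcs[, has_wind, drop = FALSE], 1, which.min)]
    tt <- (doy_all[j] - 1) / (ndays_year - 1)
    nc <- data.frame(
      day_lst = lst$day[gi, j], night_lst = lst$night[gi, j],
      imputed_day = lst$imputed_day[gi, j],
      imputed_night = lst$imputed_night[gi, j],
      ndvi = grid$ndvi[gi, month_all[j]],
      sin_time = sin(2 * pi * tt), cos_time = cos(2 * pi * tt),
      elev = cells$elev_m,
      wind = Wm[cbind(nearest, jj)],
      season = season_of_month(month_all[j]),
      day = doy_all[j]
    )
    p <- predict(fit, nc)
    out[, k] <- p
    new_day_flag[k] <- any(attr(p, "new_day"))
  }
  attr(out, "new_day") <- new_day_flag
  out
}
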