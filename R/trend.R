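# Exploratory data analysis, log10 transform, and spatio-temporal detrending.
# The trend surface is a tensor-product penalized regression spline in
# (lon, lat, month) with smoothness chosen by GCV -- the role a GAMM plays in
# classical treatments -- optionally with a ridge-penalized per-station
# intercept standing in for station random effects. Kriging then models the
# detrended log10 residuals.

#' Exploratory summary of a station series
#'
#' Per-station basic statistics (min, max, mean, sd, coefficient of variation,
#' skewness, excess kurtosis), a pooled Kolmogorov-Smirnov test against a
#' normal with the sample mean and sd, and a Kruskal-Wallis test of the
#' hypothesis that all stations share one distribution.
#'
#' @param data Long series tibble.
#' @return An object of class `eda_summary` with elements `per_station`
#'   (tibble), `ks` (D, p), `kw` (statistic, df, p) and `n_stations`,
#'   `n_times`. Note the K-S p-value is computed with estimated parameters
#'   and is therefore conservative (Lilliefors effect).
#' @export
eda_summary <- function(data) {
  check_cols(data, c("station_id", "time_index", "value"), "data")
  check_complete(data)
  per_station <- data |>
    dplyr::group_by(.data$station_id) |>
    dplyr::summarise(
      min = min(.data$value), max = max(.data$value),
      mean = mean(.data$value), sd = sd(.data$value),
      cv = 100 * sd(.data$value) / mean(.data$value),
      skew = moment_skewness(.data$value),
      kurtosis = moment_kurtosis(.data$value),
      .groups = "drop"
    )
  pooled <- data$value
  ks <- suppressWarnings(ks.test(pooled, "pnorm", mean(pooled), sd(pooled)))
  kw <- if (dplyr::n_distinct(data$station_id) >= 2) {
    kruskal.test(data$value, factor(data$station_id))
  } else {
    list(statistic = NA_real_, parameter = NA_real_, p.value = NA_real_)
  }
  structure(
    list(
      per_station = per_station,
      ks = tibble::tibble(D = unname(ks$statistic), p = ks$p.value),
      kw = tibble::tibble(statistic = unname(kw$statistic),
                          df = unname(kw$parameter), p = kw$p.value),
      n_stations = dplyr::n_distinct(data$station_id),
      n_times = dplyr::n_distinct(data$time_index)
    ),
    class = "eda_summary"
  )
}

#' @export
print.eda_summary <- function(x, ...) {
  cat(sprintf("EDA: %d stations x %d months\n", x$n_stations, x$n_times))
  cat(sprintf("  pooled K-S vs normal: D = %.5f, p = %.4g\n", x$ks$D, x$ks$p))
  cat(sprintf("  Kruskal-Wallis across stations: chi2 = %.4g, p = %.4g\n",
              x$kw$statistic, x$kw$p))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.eda_summary <- function(x, ...) x$per_station

#' @exportS3Method generics::glance
glance.eda_summary <- function(x, ...) {
  tibble::tibble(
    n_stations = x$n_stations, n_times = x$n_times,
    ks_D = x$ks$D, ks_p = x$ks$p,
    kw_statistic = x$kw$statistic, kw_p = x$kw$p
  )
}

#' Log10-transform a series (and back)
#'
#' @param data Long series tibble with strictly positive values.
#' @return `transform_log10()`: the tibble with `value` replaced by its log10;
#'   `untransform_log10()` inverts it.
#' @export
transform_log10 <- function(data) {
  bad <- data$value <= 0
  if (any(bad)) {
    loc <- data[bad, c("station_id", "time_index")]
    abort(sprintf(
      "log10 requires positive values; non-positive at e.g. station %s, month %s.",
      loc$station_id[1], loc$time_index[1]
    ))
  }
  dplyr::mutate(data, value = log10(.data$value))
}

#' @rdname transform_log10
#' @export
untransform_log10 <- function(data) {
  dplyr::mutate(data, value = 10^.data$value)
}

#' Fit a spatio-temporal trend to a log-scale series
#'
#' @param data Long series tibble (log10 scale for the kriging pipeline).
#' @param stations Station tibble.
#' @param kind `"tensor_spline"` (a tensor-product cubic regression spline
#'   over lon and lat plus a cubic regression spline in the month index, with
#'   GCV-selected smoothing), `"linear_surface"` (first-order surface in lon,
#'   lat, month), or `"constant"` (grand mean). The separate temporal smooth
#'   gives the month effect enough resolution to track a six-month seasonal
#'   cycle over many years, which a low-rank full space-time tensor cannot.
#' @param k_space Marginal basis dimension per spatial coordinate.
#' @param k_time Temporal basis dimension; default `min(44, max(8, T / 2))`,
#'   sized so that a six-month cycle retains several degrees of freedom per
#'   period.
#' @param station_effect Add a ridge-penalized per-station intercept.
#' @param sp Optional fixed smoothing parameters (bypasses GCV; used to hold
#'   the smoothness fixed across cross-validation refits).
#' @return An object of class `trend_fit` with the fitted model, `fitted` and
#'   `residuals` long tibbles (fitted + residual = observed), the GCV score,
#'   and the smoothing parameters.
#' @export
fit_trend <- function(data, stations, kind = c("tensor_spline", "linear_surface", "constant"),
                      k_space = 5, k_time = NULL, station_effect = FALSE, sp = NULL) {
  kind <- match.arg(kind)
  check_complete(data)
  df <- dplyr::inner_join(data, stations[, c("station_id", "lon", "lat")],
                          by = "station_id")
  df$t <- as.numeric(df$time_index)
  df$station <- factor(df$station_id)
  n_t <- dplyr::n_distinct(df$time_index)
  k_time <- k_time %||% min(44, max(8, floor(n_t / 2)))
  if (kind == "tensor_spline") {
    if (k_space > dplyr::n_distinct(df$lon) || k_space > dplyr::n_distinct(df$lat)) {
      abort("`k_space` exceeds the number of distinct coordinates.")
    }
    if (k_time > n_t) abort("`k_time` exceeds the number of months.")
    form <- value ~ te(lon, lat, bs = c("cr", "cr"), k = c(k_space, k_space)) +
      s(t, bs = "cr", k = k_time)
    if (station_effect) {
      form <- stats::update.formula(form, . ~ . + s(station, bs = "re"))
    }
    model <- mgcv::gam(form, data = df, method = "GCV.Cp", sp = sp)
    fitted_vals <- unname(fitted(model))
    gcv <- unname(model$gcv.ubre)
    sp_out <- model$sp
  } else {
    form <- switch(kind, constant = value ~ 1, linear_surface = value ~ lon + lat + t)
    model <- lm(form, data = df)
    fitted_vals <- unname(fitted(model))
    p <- length(coef(model))
    n <- nrow(df)
    gcv <- n * sum(residuals(model)^2) / (n - p)^2
    sp_out <- NULL
  }
  structure(
    list(
      model = model, kind = kind, station_effect = station_effect,
      k_space = k_space, k_time = k_time, sp = sp_out, gcv = gcv,
      fitted = dplyr::mutate(data[, c("station_id", "time_index")], value = fitted_vals),
      residuals = dplyr::mutate(data[, c("station_id", "time_index")],
                                value = data$value - fitted_vals),
      observed = data
    ),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Spatio-temporal trend fit (%s), GCV = %.6g\n", x$kind, x$gcv))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.trend_fit <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, gcv = x$gcv,
    r_squared = 1 - var(x$residuals$value) / var(x$observed$value),
    edf = if (inherits(x$model, "gam")) sum(x$model$edf) else length(coef(x$model))
  )
}

#' Predict the fitted trend at station locations and months
#'
#' @param fit A [fit_trend()] object.
#' @param stations Station tibble rows to predict for (may include stations
#'   absent from the training data; any station random effect is excluded for
#'   such predictions).
#' @param time_index Months to predict at.
#' @return Long tibble `station_id`, `time_index`, `value` of trend values.
#' @export
predict_trend <- function(fit, stations, time_index) {
  nd <- tidyr::expand_grid(
    station_id = stations$station_id,
    time_index = as.integer(time_index)
  ) |>
    dplyr::inner_join(stations[, c("station_id", "lon", "lat")], by = "station_id")
  nd$t <- as.numeric(nd$time_index)
  if (inherits(fit$model, "gam")) {
    if (fit$station_effect) {
      nd$station <- factor(nd$station_id, levels = levels(fit$model$model$station))
      known <- !is.na(nd$station)
      nd$station[!known] <- levels(fit$model$model$station)[1]
      pred <- predict(fit$model, newdata = nd,
                      exclude = if (all(known)) NULL else "s(station)")
    } else {
      pred <- predict(fit$model, newdata = nd)
    }
  } else {
    pred <- predict(fit$model, newdata = nd)
  }
  tibble::tibble(
    station_id = nd$station_id, time_index = nd$time_index,
    value = unname(as.numeric(pred))
  )
}

#' Residual diagnostics for a trend fit
#'
#' Kolmogorov-Smirnov test of the standardized residuals against the standard
#' normal, a quantile-quantile deviation summary, and a heteroscedasticity
#' check (slope of |residual| on fitted values with its p-value).
#'
#' @param fit A [fit_trend()] object.
#' @return One-row tibble with `ks_D`, `ks_p`, `qq_max_abs_dev`, `het_slope`,
#'   `het_p`, `degenerate` (TRUE when the residuals have essentially zero
#'   variance, in which case the other entries are NA).
#' @export
residual_diagnostics <- function(fit) {
  r <- fit$residuals$value
  f <- fit$fitted$value
  s <- sd(r)
  if (!is.finite(s) || s < 1e-12 * max(1, sd(fit$observed$value))) {
    return(tibble::tibble(ks_D = NA_real_, ks_p = NA_real_,
                          qq_max_abs_dev = NA_real_,
                          het_slope = NA_real_, het_p = NA_real_,
                          degenerate = TRUE))
  }
  zr <- (r - mean(r)) / s
  ks <- suppressWarnings(ks.test(zr, "pnorm"))
  pp <- (seq_along(zr) - 0.5) / length(zr)
  qq_dev <- max(abs(sort(zr) - stats::qnorm(pp)))
  het <- summary(lm(abs(r) ~ f))$coefficients
  tibble::tibble(
    ks_D = unname(ks$statistic), ks_p = ks$p.value,
    qq_max_abs_dev = qq_dev,
    het_slope = het[2, 1], het_p = het[2, 4],
    degenerate = FALSE
  )
}

#' Stepwise detrending escalation
#'
#' Applies the classical escalation used before kriging: test the raw series
#' for normality; if it fails, log10-transform; if normality still fails,
#' remove a first-order linear surface; if the residuals still fail, fit the
#' tensor-product spline trend. Each branch taken is recorded.
#'
#' @param data Long series tibble (raw scale, positive values).
#' @param stations Station tibble.
#' @param alpha Significance level for the K-S (and heteroscedasticity)
#'   checks.
#' @param ... Passed to [fit_trend()] for the model-based levels.
#' @return List with `level` (one of `"raw"`, `"log10"`, `"linear_surface"`,
#'   `"tensor_spline"`), `fit` (a [fit_trend()] object or `NULL`),
#'   `residuals` (long tibble on the log10 scale, or `NULL` for level
#'   `"raw"`), and `log` (character vector of decisions).
#' @export
detrend_escalate <- function(data, stations, alpha = 0.05, ...) {
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  eda_raw <- eda_summary(data)
  note("EDA raw: K-S D = %.5f, p = %.4g", eda_raw$ks$D, eda_raw$ks$p)
  if (eda_raw$ks$p >= alpha) {
    note("Raw series passes normality at alpha = %g; no transformation.", alpha)
    return(list(level = "raw", fit = NULL, residuals = NULL, log = log_lines))
  }
  note("Raw series fails normality; applying log10 transform.")
  data_log <- transform_log10(data)
  eda_log <- eda_summary(data_log)
  note("EDA log10: K-S D = %.5f, p = %.4g", eda_log$ks$D, eda_log$ks$p)
  if (eda_log$ks$p >= alpha) {
    return(list(level = "log10", fit = NULL, residuals = data_log, log = log_lines))
  }
  note("log10 series fails normality; removing linear surface.")
  fit_lin <- fit_trend(data_log, stations, kind = "linear_surface")
  diag_lin <- residual_diagnostics(fit_lin)
  note("Linear-surface residuals: K-S D = %.5f, p = %.4g; het p = %.4g",
       diag_lin$ks_D, diag_lin$ks_p, diag_lin$het_p)
  if (!isTRUE(diag_lin$degenerate) && diag_lin$ks_p >= alpha && diag_lin$het_p >= alpha) {
    return(list(level = "linear_surface", fit = fit_lin,
                residuals = fit_lin$residuals, log = log_lines))
  }
  note("Linear surface insufficient; fitting tensor-product spline trend.")
  fit_gam <- fit_trend(data_log, stations, kind = "tensor_spline", ...)
  diag_gam <- residual_diagnostics(fit_gam)
  note("Spline-trend residuals: K-S D = %.5f, p = %.4g", diag_gam$ks_D, diag_gam$ks_p)
  list(level = "tensor_spline", fit = fit_gam, residuals = fit_gam$residuals,
       log = log_lines)
}
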