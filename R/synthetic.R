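# Synthetic monthly PM2.5 fields on a regular station grid. The generator is
# lognormal by construction: a strictly positive deterministic trend (spatial
# gradient + six-month seasonal cycle) is perturbed on the log10 scale by a
# zero-mean Gaussian process with separable exponential space-time correlation
# plus an iid nugget, and multiplicative outliers are injected on the raw
# scale.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Simulate a separable space-time Gaussian process on a station grid
#'
#' Draws one realization of a zero-mean Gaussian field over stations x months
#' whose covariance is `C(h, tau) = sill * (1 - gs(h)) * (1 - gt(tau))`, the
#' covariance companion of the separable variogram. The draw uses the
#' Kronecker factorization of the spatial and temporal Cholesky factors, so
#' the covariance is exact at O(n^3 + T^3) cost.
#'
#' @param stations Station tibble (`lon`, `lat`).
#' @param n_times Number of months.
#' @param spatial,temporal Marginal variogram models from [vgm_model()]
#'   (ranges in km and months respectively).
#' @param sill Marginal variance of the field.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @param convention Distance convention for spatial lags.
#' @return Numeric matrix `n_stations x n_times`.
#' @export
simulate_separable_gp <- function(stations, n_times, spatial, temporal, sill,
                                  seed = NULL,
                                  convention = c("great_circle_km", "euclidean_degrees")) {
  convention <- match.arg(convention)
  stopifnot(sill >= 0, n_times >= 1)
  n <- nrow(stations)
  if (sill == 0) {
    return(matrix(0, n, n_times, dimnames = list(stations$station_id, seq_len(n_times))))
  }
  Cs <- 1 - vgm_eval(spatial, pairwise_distance(stations, convention))
  Ct <- 1 - vgm_eval(temporal, abs(outer(seq_len(n_times), seq_len(n_times), "-")))
  Ls <- chol_psd(Cs, "spatial")
  Lt <- chol_psd(Ct, "temporal")
  with_seed(seed, {
    z <- matrix(rnorm(n * n_times), n, n_times)
    out <- sqrt(sill) * (Ls %*% z %*% t(Lt))
    dimnames(out) <- list(stations$station_id, seq_len(n_times))
    out
  })
}

chol_psd <- function(m, what) {
  ch <- tryCatch(t(chol(m)), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- eigen(m, symmetric = TRUE)
    if (min(ev$values) < -1e-8 * max(abs(ev$values))) {
      abort(sprintf(
        "%s covariance is not positive definite (condition number %.3g).",
        what, max(ev$values) / max(min(ev$values), .Machine$double.eps)
      ))
    }
    ch <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))
  }
  ch
}

#' Simulate a synthetic monthly PM2.5 station-grid series
#'
#' Generates a complete station x month concentration series with the
#' statistical signatures of monthly reanalysis PM2.5 over a coastal desert
#' region: a smooth spatial gradient, a clear seasonal cycle peaking every six
#' months, positive skew with occasional outliers, and separable space-time
#' correlation. The construction is
#' `value = 10^(log10(trend) + GP) * outlier_factor` with
#' `trend = base_level + gradient . (lon - lon_c, lat - lat_c) +
#' seasonal_amplitude * cos(2 pi t / seasonal_period)` (gradients are centred
#' on the grid centroid so `base_level` is the domain-mean level) and GP a
#' zero-mean Gaussian process on the log10 scale with separable exponential
#' correlation, total variance `sill_log`, of which `nugget_fraction` is iid.
#'
#' @param n_rows,n_cols,n_times Grid dimensions and number of months.
#' @param base_level Domain-mean concentration of the noise-free trend, ug/m3.
#' @param gradient_lon,gradient_lat Spatial gradient of the trend, ug/m3 per
#'   degree.
#' @param seasonal_amplitude Amplitude of the seasonal cosine, ug/m3.
#' @param seasonal_period Months between seasonal peaks.
#' @param spatial_range,temporal_range Exponential correlation ranges of the
#'   log-scale field (km, months).
#' @param sill_log Total variance of the log10-scale field.
#' @param nugget_fraction Fraction of `sill_log` realized as iid noise, in
#'   `[0, 1)`.
#' @param outlier_rate Per-cell probability of a multiplicative outlier, in
#'   `[0, 0.05]`.
#' @param outlier_multiplier Raw-scale factor applied to outlier cells (>= 1).
#' @param seed Integer seed; the output is deterministic for a fixed seed.
#' @param lon0,lat0,spacing_lon,spacing_lat Grid geometry, see [make_grid()].
#' @return An object of class `pm25_sim`: a list with tibbles `stations` and
#'   `data` (long series), the noise-free `trend` (long), and the generator
#'   `params`.
#' @examples
#' sim <- simulate_pm25(n_rows = 3, n_cols = 4, n_times = 24, seed = 1)
#' dplyr::count(sim$data, station_id)
#' @export
simulate_pm25 <- function(n_rows = 7, n_cols = 10, n_times = 88,
                          base_level = 70, gradient_lon = 6, gradient_lat = -4,
                          seasonal_amplitude = 25, seasonal_period = 6,
                          spatial_range = 200, temporal_range = 3,
                          sill_log = 0.01, nugget_fraction = 0.05,
                          outlier_rate = 0.01, outlier_multiplier = 1.5,
                          seed = 20240225,
                          lon0 = 52, lat0 = 26,
                          spacing_lon = 0.625, spacing_lat = 0.5) {
  stopifnot(
    sill_log >= 0, nugget_fraction >= 0, nugget_fraction < 1,
    outlier_rate >= 0, outlier_rate <= 0.05, outlier_multiplier >= 1,
    seasonal_period >= 1
  )
  stations <- make_grid(n_rows, n_cols, lon0, lat0, spacing_lon, spacing_lat)
  t_idx <- seq_len(n_times)
  spatial_part <- base_level +
    gradient_lon * (stations$lon - mean(stations$lon)) +
    gradient_lat * (stations$lat - mean(stations$lat))
  trend <- outer(spatial_part, seasonal_amplitude * cos(2 * pi * t_idx / seasonal_period), "+")
  if (any(trend <= 0)) {
    abort("Noise-free trend is non-positive somewhere; reduce gradients/amplitude or raise base_level.")
  }
  dimnames(trend) <- list(stations$station_id, t_idx)
  values <- with_seed(seed, {
    gp <- if (sill_log > 0) {
      smooth <- simulate_separable_gp(
        stations, n_times,
        spatial = vgm_model("exponential", range = spatial_range),
        temporal = vgm_model("exponential", range = temporal_range),
        sill = sill_log * (1 - nugget_fraction), seed = NULL
      )
      smooth + matrix(rnorm(n_rows * n_cols * n_times, 0,
                            sqrt(sill_log * nugget_fraction)),
                      n_rows * n_cols, n_times)
    } else {
      matrix(0, n_rows * n_cols, n_times)
    }
    v <- 10^(log10(trend) + gp)
    if (outlier_rate > 0) {
      hit <- matrix(runif(length(v)) < outlier_rate, nrow(v), ncol(v))
      v[hit] <- v[hit] * outlier_multiplier
    }
    v
  })
  dimnames(values) <- dimnames(trend)
  structure(
    list(
      stations = stations,
      data = matrix_series(values),
      trend = matrix_series(trend),
      params = list(
        n_rows = n_rows, n_cols = n_cols, n_times = n_times,
        base_level = base_level, gradient_lon = gradient_lon,
        gradient_lat = gradient_lat, seasonal_amplitude = seasonal_amplitude,
        seasonal_period = seasonal_period, spatial_range = spatial_range,
        temporal_range = temporal_range, sill_log = sill_log,
        nugget_fraction = nugget_fraction, outlier_rate = outlier_rate,
        outlier_multiplier = outlier_multiplier, seed = seed
      )
    ),
    class = "pm25_sim"
  )
}

#' @export
print.pm25_sim <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Synthetic PM2.5 field: %d x %d stations, %d months (seed %s)\n",
    p$n_rows, p$n_cols, p$n_times, format(p$seed)
  ))
  cat(sprintf(
    "  base %g ug/m3, seasonal amplitude %g (period %g mo), sill_log %g\n",
    p$base_level, p$seasonal_amplitude, p$seasonal_period, p$sill_log
  ))
  invisible(x)
}
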