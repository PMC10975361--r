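# Ordinary spatio-temporal kriging under the separable covariance
# C(h, tau) = sill * (1 - gs(h)) * (1 - gt(tau)). Because the covariance
# factorizes, the data covariance over (stations x months) is a Kronecker
# product, and for a fixed target location the kriging weights depend only on
# the pattern of temporal offsets in the neighborhood window -- interior
# months share one solve.

#' Ordinary kriging of a station series at a new location
#'
#' Solves the ordinary kriging system `[C 1; 1' 0] [w; lambda] = [c0; 1]` with
#' covariances from the separable model, using all stations and the `k_t`
#' nearest months as the neighborhood for each target month. Weights sum to
#' one on every solve; with zero nuggets the predictor is exact at data
#' points.
#'
#' @param data Long series tibble of (typically detrended log) residuals.
#' @param stations Station tibble (the data support).
#' @param model A [sep_vgm()] object.
#' @param lon,lat Target location (one point).
#' @param times Target months (within the data window).
#' @param k_t Number of nearest months in the neighborhood (capped at T).
#' @param convention Distance convention.
#' @return Tibble with `time_index`, `pred`, `var` (kriging variance).
#' @export
krige_st <- function(data, stations, model, lon, lat, times = NULL, k_t = 5,
                     convention = c("great_circle_km", "euclidean_degrees")) {
  convention <- match.arg(convention)
  z <- series_matrix(data)
  stations <- dplyr::arrange(tibble::as_tibble(stations), .data$station_id)
  stopifnot(identical(as.integer(rownames(z)), as.integer(stations$station_id)))
  t_all <- as.integer(colnames(z))
  times <- as.integer(times %||% t_all)
  if (any(!(times %in% t_all))) abort("Target months must lie within the data window.")
  k_t <- min(k_t, length(t_all))
  As <- 1 - vgm_eval(model$spatial, pairwise_distance(stations, convention))
  cs <- model$sill * (1 - vgm_eval(model$spatial, distance_to(stations, lon, lat, convention)))
  gt_of <- function(tau) 1 - vgm_eval(model$temporal, tau)
  cache <- new.env(parent = emptyenv())
  out <- purrr::map_dfr(times, function(t0) {
    ord <- order(abs(t_all - t0), t_all)
    W <- sort(t_all[ord[seq_len(k_t)]])
    delta <- W - t0
    key <- paste(delta, collapse = ",")
    sol <- cache[[key]]
    if (is.null(sol)) {
      At <- gt_of(abs(outer(delta, delta, "-")))
      C <- model$sill * kronecker(At, As)
      c0 <- kronecker(gt_of(abs(delta)), cs)
      m <- length(c0)
      A <- rbind(cbind(C, 1), c(rep(1, m), 0))
      b <- c(c0, 1)
      wl <- tryCatch(solve(A, b), error = function(e) {
        jit <- max(1e-10 * model$sill, 1e-12)
        diag(A)[seq_len(m)] <- diag(A)[seq_len(m)] + jit
        tryCatch(solve(A, b), error = function(e2) {
          abort("Kriging system is singular even after jitter.")
        })
      })
      v <- model$sill - sum(wl[seq_len(m)] * c0) - wl[m + 1]
      sol <- list(w = wl[seq_len(m)], lambda = wl[m + 1],
                  var = max(v, 0))  # clamp numerical negatives at data points
      cache[[key]] <- sol
    }
    zvec <- as.vector(z[, match(W, t_all), drop = FALSE])
    tibble::tibble(time_index = t0, pred = sum(sol$w * zvec), var = sol$var)
  })
  out
}

#' Back-transform log10-scale predictions with lognormal bias correction
#'
#' Returns `10^pred_log * 10^(sigma2 / 2)`, the retransformation with the
#' conventional correction factor `10^(sigma2/2)` where `sigma2` is the
#' variance of the log10-scale predictions. The factor is always >= 1. The
#' exact lognormal mean correction for base 10, `10^(ln(10) * sigma2 / 2)`,
#' is available behind `exact = TRUE`.
#'
#' @param pred_log Predictions on the log10 scale.
#' @param sigma2 Variance of the log10 predictions (scalar or vector, >= 0).
#' @param exact Use the exact lognormal-mean correction exponent.
#' @return Numeric vector on the original scale.
#' @examples
#' back_transform(1, 0.04)  # 10 * 10^0.02 = 10.4713
#' @export
back_transform <- function(pred_log, sigma2, exact = FALSE) {
  if (any(sigma2 < 0)) abort("`sigma2` must be non-negative.")
  expo <- if (exact) log(10) * sigma2 / 2 else sigma2 / 2
  10^pred_log * 10^expo
}
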