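# Inverse distance weighting with whole-series station-omission LOOCV and
# power-parameter selection. Predictions are convex combinations of neighbor
# values: w_i = d_i^-beta / sum_j d_j^-beta. A target coinciding with a
# neighbor returns that neighbor's value exactly (the limit of the weights).

idw_weights <- function(dists, beta) {
  zero <- dists == 0
  if (any(zero)) {
    w <- as.numeric(zero) / sum(zero)
  } else {
    w <- dists^(-beta)
    w <- w / sum(w)
  }
  w
}

#' Inverse-distance-weighted prediction at target locations
#'
#' @param points Tibble of neighbors with columns `lon`, `lat`, `value`.
#' @param targets Tibble of prediction locations with columns `lon`, `lat`.
#' @param beta Power parameter (> 0); 2 is the common inverse-squared-distance
#'   default.
#' @param convention Distance convention, see [point_distance()].
#' @return Numeric vector of predictions, one per target row.
#' @examples
#' pts <- tibble::tibble(lon = c(0, 2), lat = 0, value = c(10, 20))
#' idw_predict(pts, tibble::tibble(lon = 1, lat = 0))  # 15 (equidistant)
#' @export
idw_predict <- function(points, targets, beta = 2,
                        convention = c("great_circle_km", "euclidean_degrees")) {
  convention <- match.arg(convention)
  check_cols(points, c("lon", "lat", "value"), "points")
  check_cols(targets, c("lon", "lat"), "targets")
  if (nrow(points) == 0) abort("IDW needs at least one neighbor.")
  stopifnot(beta > 0)
  vapply(seq_len(nrow(targets)), function(i) {
    d <- point_distance(points$lon, points$lat,
                        targets$lon[i], targets$lat[i], convention)
    sum(idw_weights(d, beta) * points$value)
  }, numeric(1))
}

#' Leave-one-station-out cross-validation of IDW
#'
#' For each station, its entire monthly series is withheld and predicted, per
#' time step, from all remaining stations. Because the weights depend only on
#' geometry, each fold reduces to one weight vector applied across all months.
#'
#' @param data Long series tibble.
#' @param stations Station tibble.
#' @param beta Power parameter.
#' @inheritParams idw_predict
#' @return Tibble with `station_id`, `time_index`, `observed`, `predicted`.
#' @export
idw_loocv <- function(data, stations, beta = 2,
                      convention = c("great_circle_km", "euclidean_degrees")) {
  convention <- match.arg(convention)
  z <- series_matrix(data)
  stations <- dplyr::arrange(tibble::as_tibble(stations), .data$station_id)
  if (nrow(stations) < 3) abort("LOOCV needs at least 3 stations.")
  stopifnot(identical(as.integer(rownames(z)), as.integer(stations$station_id)))
  d <- pairwise_distance(stations, convention)
  n <- nrow(z)
  pred <- matrix(NA_real_, n, ncol(z), dimnames = dimnames(z))
  for (k in seq_len(n)) {
    w <- idw_weights(d[k, -k], beta)
    pred[k, ] <- drop(w %*% z[-k, , drop = FALSE])
  }
  fold_tibble(z, pred)
}

fold_tibble <- function(obs, pred) {
  tibble::tibble(
    station_id = rep(as.integer(rownames(obs)), times = ncol(obs)),
    time_index = rep(as.integer(colnames(obs)), each = nrow(obs)),
    observed = as.vector(obs),
    predicted = as.vector(pred)
  ) |>
    dplyr::arrange(.data$station_id, .data$time_index)
}

#' Select the IDW power parameter by LOOCV
#'
#' Runs station-omission LOOCV over a grid of power parameters and selects the
#' one minimizing the pooled RMSE over all stations and months. Ties are
#' broken toward the smaller (smoother) power.
#'
#' @param data Long series tibble.
#' @param stations Station tibble.
#' @param betas Candidate powers (default integers 1..10).
#' @inheritParams idw_predict
#' @return An object of class `idw_opt`: list with `beta` (the selected
#'   power), `scores` (tibble of beta, mae, rmse, mape), and `folds` (LOOCV
#'   predictions at the selected power).
#' @export
idw_optimize <- function(data, stations, betas = 1:10,
                         convention = c("great_circle_km", "euclidean_degrees")) {
  convention <- match.arg(convention)
  if (length(betas) == 0) abort("`betas` must be non-empty.")
  folds <- lapply(betas, function(b) idw_loocv(data, stations, b, convention))
  scores <- purrr::map2_dfr(betas, folds, function(b, f) {
    dplyr::bind_cols(tibble::tibble(beta = b),
                     error_metrics(f$observed, f$predicted))
  })
  if (any(!is.finite(scores$rmse))) abort("Non-finite LOOCV scores encountered.")
  # ties (to numerical precision relative to the data scale) go to smaller beta
  eps <- 1e-10 * sqrt(mean(data$value^2))
  best <- which(scores$rmse <= min(scores$rmse) + eps)[1]
  structure(
    list(beta = betas[best], scores = scores, folds = folds[[best]],
         convention = convention),
    class = "idw_opt"
  )
}

#' @export
print.idw_opt <- function(x, ...) {
  cat(sprintf("IDW power selection: beta* = %g (pooled LOOCV RMSE %.4g)\n",
              x$beta, min(x$scores$rmse)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.idw_opt <- function(x, ...) x$scores

#' @exportS3Method generics::glance
glance.idw_opt <- function(x, ...) {
  best <- x$scores[x$scores$beta == x$beta, ]
  tibble::tibble(beta = x$beta, mae = best$mae, rmse = best$rmse, mape = best$mape)
}
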