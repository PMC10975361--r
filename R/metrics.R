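# Error and efficiency metrics, computed per station and aggregated as
# min/max/average rows. MAPE is reported in percent. NaN inputs are an error:
# the series contract is gap-free.

check_pair <- function(obs, sim) {
  if (length(obs) != length(sim)) abort("`obs` and `sim` must have equal length.")
  if (length(obs) == 0) abort("Empty series.")
  if (any(!is.finite(obs)) || any(!is.finite(sim))) {
    abort("Non-finite values in `obs` or `sim`; metrics never drop values silently.")
  }
  invisible(NULL)
}

#' Error metrics: MAE, RMSE and MAPE
#'
#' @param obs,sim Observed and simulated series of equal length; `obs` must be
#'   non-zero for MAPE.
#' @return One-row tibble with `mae`, `rmse`, `mape` (percent).
#' @examples
#' error_metrics(c(100), c(110))  # 10, 10, 10%
#' @export
error_metrics <- function(obs, sim) {
  check_pair(obs, sim)
  if (any(obs == 0)) abort("MAPE undefined: `obs` contains zeros.")
  e <- obs - sim
  tibble::tibble(
    mae = mean(abs(e)),
    rmse = sqrt(mean(e^2)),
    mape = 100 * mean(abs(e) / abs(obs))
  )
}

#' Nash-Sutcliffe efficiency
#'
#' `1 - sum((obs - sim)^2) / sum((obs - mean(obs))^2)`. Unity is a perfect
#' match; zero means the model is only as accurate as the observed mean.
#'
#' @inheritParams error_metrics
#' @return Scalar in `(-Inf, 1]`.
#' @export
nse <- function(obs, sim) {
  check_pair(obs, sim)
  denom <- sum((obs - mean(obs))^2)
  if (denom == 0) abort("NSE undefined for constant observations.")
  1 - sum((obs - sim)^2) / denom
}

#' Kling-Gupta efficiency and its components
#'
#' `KGE = 1 - sqrt((r - 1)^2 + (alpha - 1)^2 + (beta - 1)^2)` with `r` the
#' Pearson correlation, `alpha = sd(sim)/sd(obs)` and `beta =
#' mean(sim)/mean(obs)` (this `beta` is the bias ratio, unrelated to the IDW
#' power). Standard deviations use the n-1 normalization.
#'
#' @inheritParams error_metrics
#' @return One-row tibble with `kge`, `r`, `alpha`, `beta`.
#' @export
kge <- function(obs, sim) {
  check_pair(obs, sim)
  if (length(obs) < 2) abort("KGE needs at least 2 observations.")
  if (sd(obs) == 0 || sd(sim) == 0) abort("KGE undefined for constant series.")
  if (mean(obs) == 0) abort("KGE undefined when mean(obs) is zero.")
  r <- cor(obs, sim)
  alpha <- sd(sim) / sd(obs)
  beta <- mean(sim) / mean(obs)
  tibble::tibble(
    kge = 1 - sqrt((r - 1)^2 + (alpha - 1)^2 + (beta - 1)^2),
    r = r, alpha = alpha, beta = beta
  )
}

#' Willmott's index of agreement
#'
#' `1 - sum((obs - sim)^2) / sum((|sim - mean(obs)| + |obs - mean(obs)|)^2)`,
#' the ratio of the mean square error to the potential error; lies in
#' `[0, 1]` with 1 a perfect match.
#'
#' @inheritParams error_metrics
#' @return Scalar in `[0, 1]`.
#' @export
d_index <- function(obs, sim) {
  check_pair(obs, sim)
  om <- mean(obs)
  denom <- sum((abs(sim - om) + abs(obs - om))^2)
  if (denom == 0) abort("dIndex undefined: obs and sim both constant at mean(obs).")
  1 - sum((obs - sim)^2) / denom
}

#' Per-station metrics table from LOOCV folds
#'
#' @param folds Tibble with `station_id`, `observed`, `predicted` (e.g. from
#'   [idw_loocv()], [bss_loocv()] or [stk_loocv()]).
#' @return Tibble with one row per station: `station_id`, `mae`, `rmse`,
#'   `mape`, `nse`, `kge`, `kge_r`, `kge_alpha`, `kge_beta`, `dindex`.
#' @export
station_metrics <- function(folds) {
  check_cols(folds, c("station_id", "observed", "predicted"), "folds")
  folds |>
    dplyr::group_by(.data$station_id) |>
    dplyr::group_modify(function(g, key) {
      k <- kge(g$observed, g$predicted)
      dplyr::bind_cols(
        error_metrics(g$observed, g$predicted),
        tibble::tibble(
          nse = nse(g$observed, g$predicted),
          kge = k$kge, kge_r = k$r, kge_alpha = k$alpha, kge_beta = k$beta,
          dindex = d_index(g$observed, g$predicted)
        )
      )
    }) |>
    dplyr::ungroup()
}

#' Aggregate a per-station metrics table
#'
#' @param per_station Output of [station_metrics()].
#' @return Tibble with rows `min`, `max`, `average` over stations for each
#'   metric column.
#' @export
aggregate_metrics <- function(per_station) {
  cols <- setdiff(names(per_station), "station_id")
  purrr::map_dfr(
    c(min = min, max = max, average = mean),
    function(f) dplyr::summarise(per_station, dplyr::across(dplyr::all_of(cols), f)),
    .id = "stat"
  )
}

#' Write a metrics CSV (per-station rows plus min/max/average footer)
#'
#' @param per_station Output of [station_metrics()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(per_station, path) {
  agg <- aggregate_metrics(per_station)
  body <- dplyr::mutate(per_station, station_id = as.character(.data$station_id))
  foot <- dplyr::rename(agg, station_id = "stat")
  readr::write_csv(dplyr::bind_rows(body, foot), path)
  invisible(path)
}
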