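# ggplot2 autoplot methods for the main result types.

#' @export
autoplot.emp_st_variogram <- function(object, model = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$h, y = .data$gamma,
                                        colour = factor(.data$tau))) +
    ggplot2::geom_point(ggplot2::aes(size = .data$npairs), alpha = 0.7) +
    ggplot2::scale_size_area(max_size = 3, guide = "none") +
    ggplot2::labs(x = "spatial lag", y = "semivariance", colour = "temporal lag\n(months)")
  if (!is.null(model)) {
    hh <- seq(0, max(df$h), length.out = 80)
    curves <- purrr::map_dfr(unique(df$tau), function(tau) {
      tibble::tibble(h = hh, tau = tau, gamma = sep_vgm_eval(model, hh, rep(tau, length(hh))))
    })
    p <- p + ggplot2::geom_line(data = curves,
                                ggplot2::aes(x = .data$h, y = .data$gamma,
                                             colour = factor(.data$tau)))
  }
  p
}

#' @export
autoplot.idw_opt <- function(object, ...) {
  ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$beta, y = .data$rmse)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = object$scores[object$scores$beta == object$beta, ],
                        colour = "red", size = 3) +
    ggplot2::labs(x = "power parameter", y = "pooled LOOCV RMSE")
}

#' @export
autoplot.eda_summary <- function(object, ...) {
  ggplot2::ggplot(object$per_station, ggplot2::aes(x = .data$mean)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "per-station mean concentration", y = "stations")
}

#' @export
autoplot.st_benchmark <- function(object, metric = "mae", ...) {
  df <- purrr::imap_dfr(object$metrics, function(tab, nm) {
    tibble::tibble(method = nm, station_id = tab$station_id, value = tab[[metric]])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = paste("per-station", toupper(metric)))
}

#' Observed vs predicted series plot for LOOCV folds
#'
#' @param folds Fold tibble (`station_id`, `time_index`, `observed`,
#'   `predicted`).
#' @param station_ids Stations to display.
#' @return A ggplot object.
#' @export
plot_folds <- function(folds, station_ids = unique(folds$station_id)[1:3]) {
  df <- folds |>
    dplyr::filter(.data$station_id %in% station_ids) |>
    tidyr::pivot_longer(c("observed", "predicted"), names_to = "series")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_index, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~station_id, scales = "free_y") +
    ggplot2::labs(x = "month", y = "concentration")
}
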