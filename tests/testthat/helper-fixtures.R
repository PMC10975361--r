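# Shared fixtures, built in code.

options(stinterp.verbose = FALSE)

# small deterministic series on a lattice: value = a + b*lon + c*lat + d*cos
toy_series <- function(n_rows = 3, n_cols = 4, n_times = 6,
                       a = 50, b = 2, c = -3, d = 5,
                       lon0 = 0, lat0 = 2, spacing = 1) {
  stations <- make_grid(n_rows, n_cols, lon0 = lon0, lat0 = lat0,
                        spacing_lon = spacing, spacing_lat = spacing)
  grid <- tidyr::expand_grid(station_id = stations$station_id,
                             time_index = seq_len(n_times))
  df <- dplyr::inner_join(grid, stations, by = "station_id")
  df$value <- a + b * df$lon + c * df$lat + d * cos(2 * pi * df$time_index / 6)
  list(stations = stations,
       data = df[, c("station_id", "time_index", "value")])
}

# constant-valued series
constant_series <- function(value = 10, n_rows = 3, n_cols = 3, n_times = 4) {
  stations <- make_grid(n_rows, n_cols, lon0 = 0, lat0 = n_rows - 1,
                        spacing_lon = 1, spacing_lat = 1)
  data <- tidyr::expand_grid(station_id = stations$station_id,
                             time_index = seq_len(n_times))
  data$value <- value
  list(stations = stations, data = data)
}
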