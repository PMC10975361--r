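#' Construct a regular station grid
#'
#' Builds a station table on a regular lon/lat lattice. Stations are numbered
#' 1-based in row-major order (row 1 is the northernmost), so on a 7 x 10 grid
#' the corners carry ids 1, 10, 61 and 70. Latitude decreases with row index.
#'
#' @param n_rows,n_cols Number of lattice rows (latitudes) and columns
#'   (longitudes).
#' @param lon0,lat0 Coordinates of station 1 (north-west corner), decimal
#'   degrees.
#' @param spacing_lon,spacing_lat Lattice spacing in degrees (both positive;
#'   latitude decreases southwards by `spacing_lat` per row).
#' @return A tibble with columns `station_id`, `lon`, `lat`, `grid_row`,
#'   `grid_col` (0-based indices).
#' @examples
#' make_grid(2, 3, lon0 = 0, lat0 = 1, spacing_lon = 1, spacing_lat = 1)
#' @export
make_grid <- function(n_rows = 7, n_cols = 10, lon0 = 52, lat0 = 26,
                      spacing_lon = 0.625, spacing_lat = 0.5) {
  stopifnot(n_rows >= 1, n_cols >= 1, spacing_lon > 0, spacing_lat > 0)
  grid_row <- rep(seq_len(n_rows) - 1L, each = n_cols)
  grid_col <- rep(seq_len(n_cols) - 1L, times = n_rows)
  tibble::tibble(
    station_id = seq_len(n_rows * n_cols),
    lon = lon0 + grid_col * spacing_lon,
    lat = lat0 - grid_row * spacing_lat,
    grid_row = grid_row,
    grid_col = grid_col
  )
}

#' Detect a regular lattice in station coordinates
#'
#' Checks whether the stations form a complete regular lon/lat lattice and, if
#' so, returns its dimensions and spacings. Detection is invariant to the row
#' order of the input.
#'
#' @param stations Data frame with columns `station_id`, `lon`, `lat`.
#' @param tol Absolute tolerance in degrees when matching coordinates to
#'   lattice lines.
#' @return A list with elements `gridded` (logical), and when `gridded` is
#'   `TRUE`: `n_rows`, `n_cols`, `spacing_lon`, `spacing_lat`, and a `stations`
#'   tibble augmented with `grid_row`/`grid_col` (0-based, row-major from the
#'   north-west corner).
#' @export
detect_lattice <- function(stations, tol = 1e-6) {
  check_cols(stations, c("station_id", "lon", "lat"), "stations")
  lons <- sort(unique(round(stations$lon / tol) * tol))
  lats <- sort(unique(round(stations$lat / tol) * tol))
  # collapse near-duplicates
  collapse <- function(v) v[c(TRUE, diff(v) > tol)]
  lons <- collapse(lons)
  lats <- collapse(lats)
  n_cols <- length(lons)
  n_rows <- length(lats)
  ok <- nrow(stations) == n_rows * n_cols && n_rows >= 2 && n_cols >= 2
  if (ok) {
    dl <- diff(lons)
    db <- diff(lats)
    ok <- all(abs(dl - dl[1]) <= tol) && all(abs(db - db[1]) <= tol)
  }
  if (ok) {
    # every (lat, lon) cell occupied exactly once
    ij <- paste(
      findInterval(stations$lat, lats - tol / 2),
      findInterval(stations$lon, lons - tol / 2)
    )
    ok <- !anyDuplicated(ij)
  }
  if (!ok) {
    return(list(gridded = FALSE, stations = tibble::as_tibble(stations)))
  }
  out <- tibble::as_tibble(stations)
  out$grid_col <- findInterval(out$lon, lons - tol / 2) - 1L
  # row 0 is the northernmost latitude
  out$grid_row <- n_rows - findInterval(out$lat, lats - tol / 2)
  list(
    gridded = TRUE,
    n_rows = n_rows,
    n_cols = n_cols,
    spacing_lon = if (n_cols > 1) diff(lons)[1] else NA_real_,
    spacing_lat = if (n_rows > 1) diff(lats)[1] else NA_real_,
    stations = out
  )
}

#' Read a station table from CSV
#'
#' Reads `station_id`, `lon`, `lat` columns, validates them, and infers the
#' row/column structure when the coordinates form a regular lattice. Irregular
#' layouts are accepted but returned without `grid_row`/`grid_col` indices.
#'
#' @param path Path to a CSV file with columns `station_id`, `lon`, `lat`.
#' @return A tibble of stations; when the layout is a regular lattice it
#'   carries `grid_row`/`grid_col` columns.
#' @export
read_stations <- function(path) {
  if (!file.exists(path)) abort(sprintf("Station file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_cols(df, c("station_id", "lon", "lat"), "stations")
  if (anyDuplicated(df$station_id)) abort("Duplicate station ids in station table.")
  if (!is.numeric(df$lon) || !is.numeric(df$lat)) {
    abort("Station coordinates must be numeric.")
  }
  lat <- detect_lattice(df)
  if (!lat$gridded) {
    st_log("Station layout is not a regular lattice; grid indices omitted.", level = "WARN")
    return(dplyr::arrange(tibble::as_tibble(df), .data$station_id))
  }
  dplyr::arrange(lat$stations, .data$station_id)
}

#' Write a station table to CSV
#'
#' @param stations Station tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stations <- function(stations, path) {
  readr::write_csv(stations, path)
  invisible(path)
}

grid_spacing <- function(stations) {
  lat <- detect_lattice(stations)
  if (!lat$gridded) abort("Stations do not form a regular lattice.")
  lat
}
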