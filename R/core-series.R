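# Station x time concentration series. The canonical in-memory form is a long
# tibble (station_id, time_index, value) with values in ug/m3 and time indexed
# by integer month 1..T; a dense matrix view is available via series_matrix().

#' Convert a long series tibble to a station x time matrix
#'
#' @param data Long tibble with `station_id`, `time_index`, `value`; every
#'   (station, time) cell must be present exactly once.
#' @return Numeric matrix, rows ordered by `station_id` (rownames), columns by
#'   `time_index`.
#' @export
series_matrix <- function(data) {
  check_cols(data, c("station_id", "time_index", "value"), "data")
  ids <- sort(unique(data$station_id))
  times <- sort(unique(data$time_index))
  check_complete(data, ids, times)
  m <- matrix(NA_real_, length(ids), length(times),
              dimnames = list(ids, times))
  m[cbind(match(data$station_id, ids), match(data$time_index, times))] <- data$value
  m
}

#' Convert a station x time matrix to a long series tibble
#'
#' @param m Numeric matrix with station ids as rownames and time indices as
#'   colnames (defaults to 1..n when absent).
#' @return Long tibble with `station_id`, `time_index`, `value`, ordered by
#'   station then time.
#' @export
matrix_series <- function(m) {
  ids <- as.integer(rownames(m) %||% seq_len(nrow(m)))
  times <- as.integer(colnames(m) %||% seq_len(ncol(m)))
  tibble::tibble(
    station_id = rep(ids, times = ncol(m)),
    time_index = rep(times, each = nrow(m)),
    value = as.vector(m)
  ) |>
    dplyr::arrange(.data$station_id, .data$time_index)
}

check_complete <- function(data, ids = sort(unique(data$station_id)),
                           times = sort(unique(data$time_index))) {
  full <- expand.grid(station_id = ids, time_index = times)
  key <- paste(data$station_id, data$time_index)
  fkey <- paste(full$station_id, full$time_index)
  gaps <- setdiff(fkey, key)
  if (length(gaps) > 0) {
    abort(sprintf(
      "Series has %d missing (station, time) cell(s), e.g.: %s",
      length(gaps), paste(head(gaps, 5), collapse = "; ")
    ))
  }
  dup <- duplicated(key)
  if (any(dup)) {
    abort(sprintf(
      "Series has duplicated (station, time) cell(s), e.g.: %s",
      paste(head(key[dup], 5), collapse = "; ")
    ))
  }
  invisible(data)
}

# Values read on the kg/m3 scale (~1e-8..1e-7) are converted to ug/m3.
maybe_convert_units <- function(values) {
  med <- median(abs(values[values != 0]))
  if (is.finite(med) && med < 1e-5) {
    warn("Values look like kg/m3 (magnitude ~1e-8..1e-7); converting to ug/m3 by 1e9.")
    values <- values * 1e9
  }
  values
}

#' Read a concentration series from CSV or NetCDF
#'
#' Supported layouts: long CSV (`station_id,time_index,value`), wide CSV
#' (first column `station_id`, remaining columns `t1..tT`), and CF-style
#' NetCDF with dimensions (time, lat, lon) or (time, station). Values detected
#' on the kg/m3 scale are converted to ug/m3 with a warning. Gaps are an
#' error naming the missing cells.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension and header), `"csv_long"`,
#'   `"csv_wide"`, or `"netcdf"`.
#' @param var NetCDF variable name; defaults to the first non-coordinate
#'   variable.
#' @return Long tibble with `station_id`, `time_index`, `value` (ug/m3).
#' @export
read_series <- function(path, format = c("auto", "csv_long", "csv_wide", "netcdf"),
                        var = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("Series file not found: %s", path))
  if (format == "auto") {
    if (grepl("\\.nc$", path, ignore.case = TRUE)) {
      format <- "netcdf"
    } else {
      hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
      format <- if (all(c("station_id", "time_index", "value") %in% hdr)) {
        "csv_long"
      } else {
        "csv_wide"
      }
    }
  }
  data <- switch(format,
    csv_long = {
      df <- readr::read_csv(path, show_col_types = FALSE)
      check_cols(df, c("station_id", "time_index", "value"), "series")
      tibble::tibble(
        station_id = as.integer(df$station_id),
        time_index = as.integer(df$time_index),
        value = as.numeric(df$value)
      )
    },
    csv_wide = {
      df <- readr::read_csv(path, show_col_types = FALSE)
      if (names(df)[1] != "station_id") {
        abort("Wide series CSV must have `station_id` as its first column.")
      }
      m <- as.matrix(df[, -1, drop = FALSE])
      rownames(m) <- df$station_id
      colnames(m) <- sub("^t", "", colnames(m))
      matrix_series(m)
    },
    netcdf = read_series_netcdf(path, var)
  )
  check_complete(data)
  data$value <- maybe_convert_units(data$value)
  dplyr::arrange(data, .data$station_id, .data$time_index)
}

read_series_netcdf <- function(path, var = NULL) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (is.null(var)) {
    var <- names(nc$var)[1]
  }
  dims <- sapply(nc$var[[var]]$dim, function(d) d$name)
  vals <- ncdf4::ncvar_get(nc, var, collapse_degen = FALSE)
  if (all(c("lon", "lat", "time") %in% dims)) {
    # (lon, lat, time) on disk; stations numbered row-major from the NW corner
    lon <- ncdf4::ncvar_get(nc, "lon")
    lat <- ncdf4::ncvar_get(nc, "lat")
    vals <- aperm(vals, match(c("lon", "lat", "time"), dims))
    n_lon <- length(lon); n_lat <- length(lat)
    # order latitudes north -> south
    lat_ord <- order(lat, decreasing = TRUE)
    m <- matrix(NA_real_, n_lat * n_lon, dim(vals)[3])
    for (r in seq_len(n_lat)) {
      m[(r - 1) * n_lon + seq_len(n_lon), ] <- vals[, lat_ord[r], ]
    }
    rownames(m) <- seq_len(nrow(m))
  } else if ("station" %in% dims && "time" %in% dims) {
    vals <- aperm(vals, match(c("station", "time"), dims))
    m <- vals
    rownames(m) <- if ("station" %in% names(nc$dim)) {
      as.integer(nc$dim$station$vals)
    } else {
      seq_len(nrow(m))
    }
  } else {
    abort("NetCDF variable must have (lon, lat, time) or (station, time) dimensions.")
  }
  colnames(m) <- seq_len(ncol(m))
  matrix_series(m)
}

#' Write a concentration series to CSV or NetCDF
#'
#' @param data Long series tibble.
#' @param path Output file.
#' @param format `"csv_long"`, `"csv_wide"`, or `"netcdf"`. NetCDF output uses
#'   (time, station) dimensions, or (time, lat, lon) when `stations` describes
#'   a regular lattice.
#' @param stations Optional station tibble (required for gridded NetCDF
#'   output).
#' @param var Variable name for NetCDF output.
#' @return `path`, invisibly.
#' @export
write_series <- function(data, path, format = c("csv_long", "csv_wide", "netcdf"),
                         stations = NULL, var = "pm25") {
  format <- match.arg(format)
  check_complete(data)
  switch(format,
    csv_long = readr::write_csv(
      dplyr::arrange(data, .data$station_id, .data$time_index), path
    ),
    csv_wide = {
      m <- series_matrix(data)
      df <- tibble::as_tibble(m, .name_repair = ~ paste0("t", colnames(m)))
      df <- dplyr::bind_cols(tibble::tibble(station_id = as.integer(rownames(m))), df)
      readr::write_csv(df, path)
    },
    netcdf = write_series_netcdf(data, path, stations, var)
  )
  invisible(path)
}

write_series_netcdf <- function(data, path, stations = NULL, var = "pm25") {
  m <- series_matrix(data)
  tdim <- ncdf4::ncdim_def("time", "months since start", seq_len(ncol(m)))
  lattice <- if (!is.null(stations)) detect_lattice(stations) else list(gridded = FALSE)
  if (lattice$gridded) {
    st <- dplyr::arrange(lattice$stations, .data$station_id)
    lons <- sort(unique(st$lon))
    lats <- sort(unique(st$lat))  # netcdf convention: ascending latitude
    londim <- ncdf4::ncdim_def("lon", "degrees_east", lons)
    latdim <- ncdf4::ncdim_def("lat", "degrees_north", lats)
    v <- ncdf4::ncvar_def(var, "ug m-3", list(londim, latdim, tdim), missval = NA_real_)
    nc <- ncdf4::nc_create(path, v)
    arr <- array(NA_real_, c(length(lons), length(lats), ncol(m)))
    for (i in seq_len(nrow(st))) {
      arr[match(st$lon[i], lons), match(st$lat[i], lats), ] <- m[i, ]
    }
    ncdf4::ncvar_put(nc, v, arr)
  } else {
    sdim <- ncdf4::ncdim_def("station", "station id", as.integer(rownames(m)))
    v <- ncdf4::ncvar_def(var, "ug m-3", list(sdim, tdim), missval = NA_real_)
    nc <- ncdf4::nc_create(path, v)
    ncdf4::ncvar_put(nc, v, m)
  }
  ncdf4::nc_close(nc)
  path
}

#' Compose PM2.5 from aerosol component concentrations
#'
#' Combines the GOCART aerosol components into a PM2.5 mass concentration as
#' `1.375 * SO4 + BC + 1.6 * OC + SS2.5 + Dust2.5` (all in ug/m3), the
#' standard reanalysis surface PM2.5 recipe.
#'
#' @param so4,bc,oc,ss25,dust25 Non-negative numeric arrays of equal shape:
#'   sulfate, black carbon, organic carbon, and the fine-fraction sea salt and
#'   dust concentrations.
#' @return Numeric array of PM2.5 concentrations with the common shape.
#' @examples
#' compose_pm25(1, 1, 1, 1, 1)  # 5.975
#' @export
compose_pm25 <- function(so4, bc, oc, ss25, dust25) {
  args <- list(so4 = so4, bc = bc, oc = oc, ss25 = ss25, dust25 = dust25)
  dims <- lapply(args, function(a) dim(a) %||% length(a))
  if (length(unique(dims)) != 1) abort("All component arrays must have the same shape.")
  for (nm in names(args)) check_numeric(args[[nm]], nm)
  if (any(unlist(args) < 0)) abort("Component concentrations must be non-negative.")
  1.375 * so4 + bc + 1.6 * oc + ss25 + dust25
}
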