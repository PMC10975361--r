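# Distance conventions. The default is great-circle (haversine) distance on a
# sphere of radius 6371 km; plain Euclidean distance in degree units is
# available for parity with projected workflows.

EARTH_RADIUS_KM <- 6371

#' Distances between two sets of points
#'
#' @param lon1,lat1 Coordinates of the first set (degrees), recycled.
#' @param lon2,lat2 Coordinates of the second set (degrees), recycled.
#' @param convention `"great_circle_km"` (haversine, R = 6371 km) or
#'   `"euclidean_degrees"`.
#' @return Numeric vector of distances (km or degrees).
#' @examples
#' point_distance(0, 0, 0, 1)            # ~111.2 km
#' point_distance(0, 0, 3, 4, "euclidean_degrees")  # 5
#' @export
point_distance <- function(lon1, lat1, lon2, lat2,
                           convention = c("great_circle_km", "euclidean_degrees")) {
  convention <- match.arg(convention)
  if (convention == "euclidean_degrees") {
    return(sqrt((lon1 - lon2)^2 + (lat1 - lat2)^2))
  }
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Pairwise distance matrix between stations
#'
#' @param stations Station tibble with `lon`, `lat` (and `station_id` used for
#'   dimnames when present).
#' @inheritParams point_distance
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
pairwise_distance <- function(stations,
                              convention = c("great_circle_km", "euclidean_degrees")) {
  convention <- match.arg(convention)
  check_cols(stations, c("lon", "lat"), "stations")
  n <- nrow(stations)
  d <- outer(seq_len(n), seq_len(n), function(i, j) {
    point_distance(stations$lon[i], stations$lat[i],
                   stations$lon[j], stations$lat[j], convention)
  })
  d <- (d + t(d)) / 2  # enforce exact symmetry against rounding
  diag(d) <- 0
  if ("station_id" %in% names(stations)) {
    dimnames(d) <- list(stations$station_id, stations$station_id)
  }
  d
}

#' Distances from a set of stations to one target point
#'
#' @param stations Station tibble with `lon`, `lat`.
#' @param lon,lat Target coordinates (degrees).
#' @inheritParams point_distance
#' @return Numeric vector, one distance per station.
#' @export
distance_to <- function(stations, lon, lat,
                        convention = c("great_circle_km", "euclidean_degrees")) {
  convention <- match.arg(convention)
  point_distance(stations$lon, stations$lat, lon, lat, convention)
}
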