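#' Great-circle distance between geographic points
#'
#' Haversine distance on a sphere of radius 6371 km. Inputs are recycled, so
#' the function also computes consecutive leg lengths along a track when given
#' coordinate vectors.
#'
#' @param lon1,lat1 Coordinates of the first point(s), decimal degrees.
#' @param lon2,lat2 Coordinates of the second point(s), decimal degrees.
#' @return Distance(s) in kilometres.
#' @examples
#' great_circle_distance(0, 0, 90, 0)   # quarter circumference, ~10007.5 km
#' @export
great_circle_distance <- function(lon1, lat1, lon2, lat2) {
  check_coords(lon1, lat1)
  check_coords(lon2, lat2)
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  # clamp guards tiny negative/over-one values from floating point
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

EARTH_RADIUS_KM <- 6371

check_coords <- function(lon, lat) {
  if (any(!is.finite(lon)) || any(!is.finite(lat))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (any(lat < -90 | lat > 90)) {
    stop("latitude out of range [-90, 90]", call. = FALSE)
  }
  if (any(lon < -180 | lon >= 180)) {
    stop("longitude out of range [-180, 180)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Move a point along a bearing
#'
#' Thin wrapper over [geosphere::destPoint()] on the same 6371 km sphere used
#' by [great_circle_distance()]. Longitudes are normalised to [-180, 180).
#'
#' @param lon,lat Start point, decimal degrees.
#' @param bearing Initial bearing, degrees clockwise from north.
#' @param km Distance to travel, kilometres.
#' @return Numeric vector `c(lon, lat)` (or a two-column matrix for vector
#'   input).
#' @export
geo_destination <- function(lon, lat, bearing, km) {
  p <- geosphere::destPoint(cbind(lon, lat), bearing, km * 1000,
                            r = EARTH_RADIUS_KM * 1000)
  p[, 1] <- wrap_lon(p[, 1])
  if (nrow(p) == 1L) c(lon = p[1, 1], lat = p[1, 2]) else p
}

wrap_lon <- function(lon) {
  ((lon + 180) %% 360) - 180
}
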