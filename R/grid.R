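#' Construct an environmental grid
#'
#' A regular lon/lat grid holding one scalar field, typically bathymetry
#' (metres, negative below sea level) or net primary productivity.
#'
#' @param lon,lat Strictly increasing axis vectors, decimal degrees.
#' @param values Matrix with `length(lon)` rows and `length(lat)` columns.
#' @param name Short label for the field (e.g. `"bathymetry"`).
#' @return An object of class `env_grid`.
#' @export
env_grid <- function(lon, lat, values, name = "field") {
  if (is.unsorted(lon, strictly = TRUE) || is.unsorted(lat, strictly = TRUE)) {
    stop("grid axes must be strictly increasing", call. = FALSE)
  }
  values <- as.matrix(values)
  if (nrow(values) != length(lon) || ncol(values) != length(lat)) {
    stop("values must be a length(lon) x length(lat) matrix", call. = FALSE)
  }
  structure(list(lon = as.numeric(lon), lat = as.numeric(lat),
                 values = values, name = name),
            class = "env_grid")
}

#' Sample a gridded field at geographic points
#'
#' Nearest-node lookup. Points outside the grid's bounding box are an error:
#' the pipeline treats out-of-domain sampling as a configuration fault rather
#' than extrapolating.
#'
#' @param grid An [env_grid()].
#' @param lon,lat Query coordinates (vectorised).
#' @return Numeric vector of field values at the nearest grid node.
#' @export
sample_grid <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "env_grid"))
  if (any(lon < min(grid$lon) | lon > max(grid$lon) |
          lat < min(grid$lat) | lat > max(grid$lat))) {
    stop("point outside grid domain", call. = FALSE)
  }
  i <- vapply(lon, function(x) which.min(abs(grid$lon - x)), integer(1))
  j <- vapply(lat, function(y) which.min(abs(grid$lat - y)), integer(1))
  grid$values[cbind(i, j)]
}

#' Read and write environmental grids
#'
#' Grids are stored as plain-text long-format CSV with columns
#' `lon,lat,value` covering every node of a regular grid, so they stay
#' diffable and need no binary dependencies.
#'
#' @param grid An [env_grid()].
#' @param path File path.
#' @param name Field label applied on read.
#' @return `read_env_grid()` returns an [env_grid()]; `write_env_grid()`
#'   returns `path` invisibly.
#' @export
write_env_grid <- function(grid, path) {
  stopifnot(inherits(grid, "env_grid"))
  df <- expand.grid(lon = grid$lon, lat = grid$lat, KEEP.OUT.ATTRS = FALSE)
  df$value <- as.vector(grid$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_env_grid
#' @export
read_env_grid <- function(path, name = "field") {
  df <- utils::read.csv(path)
  need <- c("lon", "lat", "value")
  if (!all(need %in% names(df))) {
    stop("grid file must have columns lon,lat,value", call. = FALSE)
  }
  lon <- sort(unique(df$lon))
  lat <- sort(unique(df$lat))
  if (nrow(df) != length(lon) * length(lat)) {
    stop("grid file does not cover a complete regular grid", call. = FALSE)
  }
  m <- matrix(NA_real_, length(lon), length(lat))
  m[cbind(match(df$lon, lon), match(df$lat, lat))] <- df$value
  env_grid(lon, lat, m, name = name)
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("<env_grid '%s': %d x %d nodes, lon [%g, %g], lat [%g, %g]>\n",
              x$name, length(x$lon), length(x$lat),
              min(x$lon), max(x$lon), min(x$lat), max(x$lat)))
  invisible(x)
}
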