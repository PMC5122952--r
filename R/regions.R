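#' Foraging-region polygon sets
#'
#' A `forage_regions` object is a named list of polygons (two-column lon/lat
#' matrices, implicitly closed), one per region code, plus the code of the
#' region treated as coastal. The study geography uses three codes:
#' `MC` (Mozambique Channel shelf, coastal), `WIO` (Western Indian Ocean) and
#' `SAO` (South Atlantic Ocean).
#'
#' @param polygons Named list of two-column matrices (`lon`, `lat`).
#' @param coastal Region code whose polygon marks coastal habitat.
#' @return An object of class `forage_regions`.
#' @export
forage_regions <- function(polygons, coastal = "MC") {
  if (is.null(names(polygons)) || any(!nzchar(names(polygons)))) {
    stop("polygons must be a named list", call. = FALSE)
  }
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2 || nrow(p) < 3) {
      stop("each polygon needs >= 3 lon/lat vertices", call. = FALSE)
    }
    colnames(p) <- c("lon", "lat")
    p
  })
  if (!coastal %in% names(polygons)) {
    stop("coastal region '", coastal, "' not among polygons", call. = FALSE)
  }
  structure(list(polygons = polygons, coastal = coastal),
            class = "forage_regions")
}

#' Test whether points fall inside one region polygon
#'
#' @param regions A [forage_regions()] object.
#' @param region Region code.
#' @param lon,lat Query coordinates (vectorised).
#' @return Logical vector.
#' @export
in_region <- function(regions, region, lon, lat) {
  stopifnot(inherits(regions, "forage_regions"))
  poly <- regions$polygons[[region]]
  if (is.null(poly)) stop("unknown region '", region, "'", call. = FALSE)
  mgcv::in.out(poly, cbind(as.numeric(lon), as.numeric(lat)))
}

#' Find the region containing each point
#'
#' Polygons are tested in their list order; the first containing polygon
#' wins. Points inside no polygon return `"unknown"`.
#'
#' @inheritParams in_region
#' @return Character vector of region codes.
#' @export
region_lookup <- function(regions, lon, lat) {
  stopifnot(inherits(regions, "forage_regions"))
  out <- rep("unknown", length(lon))
  for (nm in names(regions$polygons)) {
    hit <- out == "unknown" & in_region(regions, nm, lon, lat)
    out[hit] <- nm
  }
  out
}

#' Read and write region polygons as GeoJSON
#'
#' Regions are exchanged as a GeoJSON FeatureCollection of Polygon features,
#' each carrying a `region` property; the coastal code travels in a
#' top-level `coastal` member (defaulting to `"MC"` when absent).
#'
#' @param regions A [forage_regions()] object.
#' @param path File path.
#' @return `read_regions()` returns a [forage_regions()] object;
#'   `write_regions()` returns `path` invisibly.
#' @export
write_regions <- function(regions, path) {
  stopifnot(inherits(regions, "forage_regions"))
  features <- lapply(names(regions$polygons), function(nm) {
    p <- regions$polygons[[nm]]
    # GeoJSON rings are explicitly closed
    ring <- rbind(p, p[1, , drop = FALSE])
    list(
      type = "Feature",
      properties = list(region = nm),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)),
                                  function(i) as.numeric(ring[i, ])))
      )
    )
  })
  obj <- list(type = "FeatureCollection", coastal = regions$coastal,
              features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_regions
#' @export
read_regions <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$type, "FeatureCollection")) {
    stop("regions file is not a GeoJSON FeatureCollection", call. = FALSE)
  }
  polys <- list()
  for (f in obj$features) {
    nm <- f$properties$region
    if (is.null(nm)) stop("feature missing 'region' property", call. = FALSE)
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(v) as.numeric(unlist(v))))
    # drop the closing vertex GeoJSON requires
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), ]
    polys[[nm]] <- m
  }
  forage_regions(polys, coastal = if (is.null(obj$coastal)) "MC" else obj$coastal)
}

#' @export
print.forage_regions <- function(x, ...) {
  cat(sprintf("<forage_regions: %s (coastal = %s)>\n",
              paste(names(x$polygons), collapse = ", "), x$coastal))
  invisible(x)
}
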