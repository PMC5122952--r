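#' Argos location-class codes, from most to least accurate
#'
#' `Z` denotes an invalid fix and is rejected at ingestion.
#' @export
LC_LEVELS <- c("3", "2", "1", "0", "A", "B")

#' Read and write Argos track tables
#'
#' Tracks are CSV with header `animal_id,timestamp,lat,lon,lc` and ISO-8601
#' UTC timestamps. Ingestion enforces the track invariants: timestamps parse,
#' coordinates are in range, location classes are known. `Z`-class fixes are
#' dropped (they carry no usable position); any other violation is rejected
#' with the offending row number. Fixes are returned sorted by animal and
#' time.
#'
#' @param path CSV file path.
#' @param tracks A track data frame (`animal_id`, `timestamp` POSIXct UTC,
#'   `lon`, `lat`, `lc`).
#' @return `read_tracks()` returns a track data frame; `write_tracks()`
#'   returns `path` invisibly.
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("animal_id", "timestamp", "lat", "lon", "lc")
  if (!all(need %in% names(df))) {
    stop("track file must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  if (nrow(df) == 0) {
    return(empty_track())
  }
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  bad <- which(is.na(ts))
  if (length(bad)) {
    stop("row ", bad[1], ": timestamp '", df$timestamp[bad[1]],
         "' is not ISO-8601 (YYYY-MM-DDTHH:MM:SS)", call. = FALSE)
  }
  lon <- suppressWarnings(as.numeric(df$lon))
  lat <- suppressWarnings(as.numeric(df$lat))
  bad <- which(is.na(lon) | is.na(lat) |
               lat < -90 | lat > 90 | lon < -180 | lon >= 180)
  if (length(bad)) {
    stop("row ", bad[1], ": invalid coordinates (", df$lon[bad[1]], ", ",
         df$lat[bad[1]], ")", call. = FALSE)
  }
  bad <- which(!df$lc %in% c(LC_LEVELS, "Z"))
  if (length(bad)) {
    stop("row ", bad[1], ": unknown location class '", df$lc[bad[1]], "'",
         call. = FALSE)
  }
  out <- data.frame(animal_id = df$animal_id, timestamp = ts,
                    lon = lon, lat = lat, lc = df$lc,
                    stringsAsFactors = FALSE)
  out <- out[out$lc != "Z", , drop = FALSE]
  out <- out[order(out$animal_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname read_tracks
#' @export
write_tracks <- function(tracks, path) {
  df <- data.frame(
    animal_id = tracks$animal_id,
    timestamp = format(tracks$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    lat = tracks$lat, lon = tracks$lon, lc = tracks$lc
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

empty_track <- function() {
  data.frame(animal_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
             lon = numeric(), lat = numeric(), lc = character(),
             stringsAsFactors = FALSE)
}

per_animal <- function(tracks, f, ...) {
  if (nrow(tracks) == 0) return(tracks)
  parts <- split(tracks, tracks$animal_id)
  out <- do.call(rbind, lapply(parts, f, ...))
  rownames(out) <- NULL
  out
}

#' Maximum-speed filter for Argos tracks
#'
#' Greedy forward sweep: each fix is compared with the last *retained* fix and
#' dropped when the implied travel speed exceeds `vmax`. The first fix of a
#' track is always retained. The sweep is deterministic and idempotent, and
#' its output never contains a consecutive pair implying a speed above
#' `vmax`. Applied per animal when `tracks` holds several.
#'
#' @param tracks Track data frame (time-ordered within animal).
#' @param vmax Maximum plausible speed, km per day. Default 240.
#' @return Filtered track data frame.
#' @export
speed_filter <- function(tracks, vmax = 240) {
  stopifnot(vmax > 0)
  per_animal(tracks, function(tr) {
    n <- nrow(tr)
    if (n <= 1) return(tr)
    keep <- logical(n)
    keep[1] <- TRUE
    last <- 1
    for (i in 2:n) {
      dt_days <- as.numeric(difftime(tr$timestamp[i], tr$timestamp[last],
                                     units = "days"))
      km <- great_circle_distance(tr$lon[last], tr$lat[last],
                                  tr$lon[i], tr$lat[i])
      # duplicate timestamps at zero displacement are kept; at nonzero
      # displacement they imply infinite speed and are dropped
      v <- if (dt_days > 0) km / dt_days else if (km == 0) 0 else Inf
      if (v <= vmax) {
        keep[i] <- TRUE
        last <- i
      }
    }
    tr[keep, , drop = FALSE]
  })
}

#' Retain the most accurate fix per UTC day
#'
#' Within each UTC calendar day, keeps the fix with the best Argos location
#' class (`3 > 2 > 1 > 0 > A > B`); ties go to the earliest fix. Applied per
#' animal. The result is a subsequence of the input.
#'
#' @param tracks Track data frame (typically speed-filtered).
#' @return Track data frame with at most one fix per animal-day.
#' @export
best_daily_fix <- function(tracks) {
  per_animal(tracks, function(tr) {
    if (nrow(tr) == 0) return(tr)
    day <- as.Date(tr$timestamp, tz = "UTC")
    rank <- match(tr$lc, LC_LEVELS)
    ord <- order(day, rank, tr$timestamp)
    tr <- tr[ord, , drop = FALSE]
    tr <- tr[!duplicated(day[ord]), , drop = FALSE]
    tr[order(tr$timestamp), , drop = FALSE]
  })
}

#' Daily travel speeds along a path
#'
#' @param path Data frame with `date`, `lon`, `lat` (one row per position,
#'   dates increasing; gaps allowed).
#' @return Data frame with one row per consecutive pair: `from`, `to`
#'   (dates), `km`, `dt_days` and `speed` (km per day).
#' @export
daily_speeds <- function(path) {
  n <- nrow(path)
  if (n < 2) stop("need at least two positions", call. = FALSE)
  i <- seq_len(n - 1)
  km <- great_circle_distance(path$lon[i], path$lat[i],
                              path$lon[i + 1], path$lat[i + 1])
  dt <- as.numeric(path$date[i + 1] - path$date[i])
  if (any(dt <= 0)) stop("dates must be strictly increasing", call. = FALSE)
  data.frame(from = path$date[i], to = path$date[i + 1],
             km = km, dt_days = dt, speed = km / dt)
}

#' Detect residence behaviour from a speed series
#'
#' Maximal runs of consecutive legs slower than `v_res` that span at least
#' `min_days` become residence segments; everything else, including short
#' slow runs (eddy-style loiters), is transit. Adjacent transit stretches are
#' merged.
#'
#' @param speed Leg speeds, km per day.
#' @param dt_days Leg durations in days (recycled; default 1).
#' @param dates Optional vector of the `length(speed) + 1` position dates;
#'   when given, segments carry `start_day`/`end_day`.
#' @param v_res Residence speed threshold, km per day. Default 5.
#' @param min_days Minimum residence duration, days. Default 15.
#' @return Data frame of segments: `start`, `end` (position indices), `mode`
#'   (`"residence"` or `"transit"`), `mean_speed` (time-weighted), `n_days`,
#'   and dates when supplied.
#' @export
detect_residence <- function(speed, dt_days = 1, dates = NULL,
                             v_res = 5, min_days = 15) {
  if (v_res < 0 || min_days < 0) stop("thresholds must be non-negative", call. = FALSE)
  m <- length(speed)
  if (m == 0) stop("empty speed series", call. = FALSE)
  dt_days <- rep_len(dt_days, m)
  slow <- speed < v_res
  r <- rle(slow)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  mode <- character(length(r$lengths))
  for (k in seq_along(r$lengths)) {
    dur <- sum(dt_days[starts[k]:ends[k]])
    mode[k] <- if (r$values[k] && dur >= min_days) "residence" else "transit"
  }
  # merge consecutive same-mode stretches (short slow runs folded into transit)
  grp <- cumsum(c(TRUE, mode[-1] != mode[-length(mode)]))
  seg <- lapply(split(seq_along(mode), grp), function(ks) {
    i1 <- starts[ks[1]]; i2 <- ends[ks[length(ks)]]
    idx <- i1:i2
    data.frame(start = i1, end = i2 + 1L, mode = mode[ks[1]],
               mean_speed = sum(speed[idx] * dt_days[idx]) / sum(dt_days[idx]),
               n_days = sum(dt_days[idx]))
  })
  out <- do.call(rbind, seg)
  rownames(out) <- NULL
  if (!is.null(dates)) {
    if (length(dates) != m + 1) {
      stop("dates must have length(speed) + 1 entries", call. = FALSE)
    }
    out$start_day <- dates[out$start]
    out$end_day <- dates[out$end]
  }
  out
}

#' Classify a track's foraging strategy
#'
#' A turtle is a coastal forager when its longest residence segment (per
#' [detect_residence()]) spends at least `shallow_frac` of its positions both
#' in water shallower than the `isobath_m` contour and inside the coastal
#' region polygon. All other tracks, including those whose only slow periods
#' are short deep-water loiters, are oceanic; the oceanic region is the
#' polygon containing the track's final position.
#'
#' @param path Data frame with `date`, `lon`, `lat`, one row per day
#'   (gaps allowed).
#' @param regions A [forage_regions()] object.
#' @param bathymetry An [env_grid()] of depths, metres, negative below sea
#'   level.
#' @param v_res,min_days Residence detection thresholds, see
#'   [detect_residence()].
#' @param isobath_m Depth contour bounding coastal habitat (default -50:
#'   shallower than 50 m).
#' @param shallow_frac Minimum fraction of residence positions that must be
#'   shallow and in the coastal polygon. Default 0.5.
#' @return A list with `strategy` (`"coastal"` or `"oceanic"`), `region`
#'   (region code or `"unknown"`), and the residence `segments` table.
#' @export
classify_strategy <- function(path, regions, bathymetry,
                              v_res = 5, min_days = 15,
                              isobath_m = -50, shallow_frac = 0.5) {
  if (missing(regions) || missing(bathymetry) ||
      is.null(regions) || is.null(bathymetry)) {
    stop("regions and bathymetry are required", call. = FALSE)
  }
  if (nrow(path) < 2) stop("path too short to classify", call. = FALSE)
  sp <- daily_speeds(path)
  seg <- detect_residence(sp$speed, sp$dt_days, dates = path$date,
                          v_res = v_res, min_days = min_days)
  res <- seg[seg$mode == "residence", , drop = FALSE]
  terminal_region <- region_lookup(regions, path$lon[nrow(path)],
                                   path$lat[nrow(path)])
  if (nrow(res) > 0) {
    best <- res[which.max(res$n_days), ]
    idx <- best$start:best$end
    depth <- sample_grid(bathymetry, path$lon[idx], path$lat[idx])
    shallow <- depth > isobath_m & depth <= 0
    incoast <- in_region(regions, regions$coastal, path$lon[idx], path$lat[idx])
    if (mean(shallow & incoast) >= shallow_frac) {
      return(list(strategy = "coastal", region = regions$coastal,
                  segments = seg))
    }
  }
  list(strategy = "oceanic", region = terminal_region, segments = seg)
}
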