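#' Configuration for synthetic study generation
#'
#' Defaults emulate the study conditions: 16 satellite-tracked and 80
#' untracked leatherbacks; coastal migrants travel ~500 km north onto a
#' shallow (< 50 m) shelf strip and sit at < 5 km per day, oceanic migrants
#' sustain long directed transits with occasional sub-15-day loiters; Argos
#' fixes arrive 0-3 per day with class-dependent Student-t noise; delta13C is
#' a two-component Normal mixture straddling the -17.5 per-mil coastal/oceanic
#' delineation, delta15N unimodal within 9.5-15.1 per mil. The mixture means
#' and movement speeds are synthetic choices (the source data are
#' unpublished), documented here and in the vignette, not field estimates.
#'
#' @param n_tracked,n_untracked Cohort sizes.
#' @param true_coastal_fraction Fraction of each cohort that truly forages
#'   coastally. Both cohorts are split exactly (rounded), so the study's true
#'   composition is the stated fraction rather than a random realisation;
#'   this also guarantees both classes appear in training.
#' @param track_days Tracking duration, days.
#' @param start Nesting-site position `c(lon, lat)`, degrees.
#' @param migration_km Coastal migration distance target, km.
#' @param transit_speed,transit_speed_sd Oceanic/migratory transit speed,
#'   km per day (Normal, floored at 20).
#' @param residence_speed Mean residence step, km per day (steps are
#'   `Uniform(0, 2 * residence_speed)`, so below 5 whenever
#'   `residence_speed <= 2.5`).
#' @param loiter_prob Probability an oceanic track contains one temporary
#'   eddy-style loiter.
#' @param loiter_days_range Loiter duration range, days (kept under 15).
#' @param p_wio Probability an oceanic migrant heads to the WIO rather than
#'   the SAO.
#' @param lc_freq,lc_scales Argos location-class frequency and noise-scale
#'   tables, see [argos_lc_freq()] and [argos_lc_scales()].
#' @param nu Observation t-distribution degrees of freedom.
#' @param fixes_per_day_probs Probabilities of 0-3 fixes per day.
#' @param outlier_prob,outlier_deg Rate and magnitude (degrees) of gross
#'   position outliers, included to exercise the maximum-speed filter.
#' @param d13c_coastal,d13c_oceanic,d13c_sd delta13C mixture parameters,
#'   per mil.
#' @param d15n_mean,d15n_sd,d15n_range delta15N distribution, per mil,
#'   clipped to the stated range.
#' @param duplicate_rate Fraction of individuals sampled twice.
#' @param rep_sd Within-individual replicate measurement noise per element
#'   (per mil), matching the duplicate-sample standard deviations the QC step
#'   screens for.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_tracked = 16, n_untracked = 80,
                             true_coastal_fraction = 0.5,
                             track_days = 110,
                             start = c(lon = 35.2, lat = -28),
                             migration_km = 500,
                             transit_speed = 40, transit_speed_sd = 5,
                             residence_speed = 1.5,
                             loiter_prob = 0.6,
                             loiter_days_range = c(5, 12),
                             p_wio = 0.65,
                             lc_freq = argos_lc_freq(),
                             lc_scales = argos_lc_scales(),
                             nu = 5,
                             fixes_per_day_probs = c(0.05, 0.25, 0.40, 0.30),
                             outlier_prob = 0.01, outlier_deg = 5,
                             d13c_coastal = -16.3, d13c_oceanic = -18.2,
                             d13c_sd = 0.5,
                             d15n_mean = 11.5, d15n_sd = 1.0,
                             d15n_range = c(9.5, 15.1),
                             duplicate_rate = 27 / 96,
                             rep_sd = c(d13C = 0.37, d15N = 0.55)) {
  stopifnot(true_coastal_fraction >= 0, true_coastal_fraction <= 1,
            d13c_sd > 0, d15n_sd > 0, track_days >= 20,
            max(loiter_days_range) < 15,
            d13c_coastal > d13c_oceanic)
  structure(as.list(environment()), class = "synthetic_config")
}

# schematic geography shared by the generator: a meridional shelf strip
# (coastal, < 50 m) flanked by deep ocean basins
GEO <- list(
  grid_lon = c(-25, 95), grid_lat = c(-60, -5), grid_step = 0.5,
  strip_lon = c(34, 36), strip_lat = c(-26, -15),
  shelf_depth = -30, ocean_depth = -3000,
  wio_lon = c(36.5, 95), sao_lon = c(-25, 33.5)
)

#' Schematic region polygons and bathymetry
#'
#' Builds the stylized study geography: a shallow (30 m) meridional shelf
#' strip standing in for the Mozambique Channel coastal habitat (`MC`),
#' flanked by 3000 m deep basins standing in for the Western Indian Ocean
#' (`WIO`, east) and South Atlantic (`SAO`, west). Deterministic.
#'
#' @param config A [synthetic_config()] (reserved for future geometry
#'   options; the geography itself is fixed).
#' @return List with `regions` (a [forage_regions()]) and `bathymetry`
#'   (an [env_grid()], metres, negative below sea level).
#' @export
make_regions_and_bathymetry <- function(config = synthetic_config()) {
  g <- GEO
  lon <- seq(g$grid_lon[1], g$grid_lon[2], by = g$grid_step)
  lat <- seq(g$grid_lat[1], g$grid_lat[2], by = g$grid_step)
  depth <- matrix(g$ocean_depth, length(lon), length(lat))
  in_strip_lon <- lon >= g$strip_lon[1] & lon <= g$strip_lon[2]
  in_strip_lat <- lat >= g$strip_lat[1] & lat <= g$strip_lat[2]
  depth[in_strip_lon, in_strip_lat] <- g$shelf_depth
  rect <- function(xr, yr) {
    cbind(lon = c(xr[1], xr[2], xr[2], xr[1]),
          lat = c(yr[1], yr[1], yr[2], yr[2]))
  }
  regions <- forage_regions(list(
    MC = rect(g$strip_lon, g$strip_lat),
    WIO = rect(g$wio_lon, g$grid_lat),
    SAO = rect(g$sao_lon, g$grid_lat)
  ), coastal = "MC")
  list(regions = regions,
       bathymetry = env_grid(lon, lat, depth, name = "bathymetry"))
}

clamp_box <- function(p) {
  g <- GEO
  c(min(max(p[1], g$grid_lon[1] + 1), g$grid_lon[2] - 1),
    min(max(p[2], g$grid_lat[1] + 1), g$grid_lat[2] - 1))
}

#' Simulate one turtle's true daily path
#'
#' Coastal strategy: a directed northward migration of about
#' `migration_km` onto the shelf strip, followed by residence with daily
#' steps below 5 km around a fixed centre. Oceanic strategy: a sustained
#' meandering transit (>= 20 km per day) towards the WIO or SAO basin,
#' optionally interrupted by one temporary loiter shorter than 15 days.
#' Randomness comes from the session RNG; call `set.seed()` for
#' reproducibility.
#'
#' @param strategy `"coastal"` or `"oceanic"`.
#' @param config A [synthetic_config()].
#' @param n_days Track length; defaults to `config$track_days`.
#' @param start_date First tracking day.
#' @return Data frame `date`, `lon`, `lat` with attributes `strategy` and
#'   `region` (the generator's intended destination region).
#' @export
simulate_turtle_track <- function(strategy, config = synthetic_config(),
                                  n_days = config$track_days,
                                  start_date = as.Date("2012-01-01")) {
  if (!strategy %in% c("coastal", "oceanic")) {
    stop("unknown strategy '", strategy, "'", call. = FALSE)
  }
  pos <- matrix(NA_real_, n_days, 2)
  pos[1, ] <- config$start
  if (strategy == "coastal") {
    region <- "MC"
    travelled <- 0
    t <- 1
    while (travelled < config$migration_km && t < n_days) {
      v <- max(20, stats::rnorm(1, config$transit_speed, config$transit_speed_sd))
      bearing <- stats::rnorm(1, 0, 8)   # northwards
      pos[t + 1, ] <- clamp_box(geo_destination(pos[t, 1], pos[t, 2], bearing, v))
      travelled <- travelled + v
      t <- t + 1
    }
    centre <- pos[t, ]
    while (t < n_days) {
      step <- stats::runif(1, 0, 2 * config$residence_speed)
      off_km <- great_circle_distance(pos[t, 1], pos[t, 2], centre[1], centre[2])
      bearing <- if (off_km > 30) {
        # drift back towards the residence centre
        geosphere::bearing(pos[t, , drop = FALSE], rbind(centre))
      } else {
        stats::runif(1, 0, 360)
      }
      pos[t + 1, ] <- clamp_box(geo_destination(pos[t, 1], pos[t, 2], bearing, step))
      t <- t + 1
    }
  } else {
    region <- if (stats::runif(1) < config$p_wio) "WIO" else "SAO"
    base_bearing <- if (region == "WIO") 80 else 245
    loiter_start <- Inf
    loiter_len <- 0
    if (stats::runif(1) < config$loiter_prob && n_days > 50) {
      loiter_len <- sample(seq(config$loiter_days_range[1],
                               config$loiter_days_range[2]), 1)
      loiter_start <- sample(seq(15, n_days - loiter_len - 5), 1)
    }
    dev <- 0
    for (t in seq_len(n_days - 1)) {
      if (t >= loiter_start && t < loiter_start + loiter_len) {
        step <- stats::runif(1, 0, 2 * config$residence_speed)
        bearing <- stats::runif(1, 0, 360)
      } else {
        dev <- max(-30, min(30, dev + stats::rnorm(1, 0, 6)))
        bearing <- base_bearing + dev
        step <- max(20, stats::rnorm(1, config$transit_speed,
                                     config$transit_speed_sd))
      }
      cand <- geo_destination(pos[t, 1], pos[t, 2], bearing, step)
      boxed <- clamp_box(cand)
      if (any(boxed != cand)) {
        # bounced off the domain edge: head back the other way
        cand <- geo_destination(pos[t, 1], pos[t, 2], bearing + 180, step)
        boxed <- clamp_box(cand)
        dev <- 0
      }
      pos[t + 1, ] <- boxed
    }
  }
  out <- data.frame(date = start_date + seq_len(n_days) - 1,
                    lon = pos[, 1], lat = pos[, 2])
  attr(out, "strategy") <- strategy
  attr(out, "region") <- region
  out
}

#' Add Argos-style observation noise to a true path
#'
#' Draws 0-3 fixes per day (at least one on the first and last day so the
#' track span is defined), assigns each a location class from the frequency
#' table, and perturbs positions with Student-t noise at the class's scale.
#' A small fraction of fixes are gross outliers several degrees off-track,
#' there to exercise the maximum-speed filter. Randomness comes from the
#' session RNG.
#'
#' @param true_path Data frame `date`, `lon`, `lat` (one row per day).
#' @param config A [synthetic_config()].
#' @param animal_id Identifier stamped on the fixes.
#' @return Track data frame (`animal_id`, `timestamp`, `lon`, `lat`, `lc`).
#' @export
add_argos_noise <- function(true_path, config = synthetic_config(),
                            animal_id = "T1") {
  n <- nrow(true_path)
  lcs <- names(config$lc_freq)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- sample(0:3, 1, prob = config$fixes_per_day_probs)
    if (i %in% c(1L, n) && k == 0) k <- 1
    if (k == 0) next
    secs <- sort(round(stats::runif(k, 0, 86399)))
    lc <- sample(lcs, k, replace = TRUE, prob = config$lc_freq)
    scale <- unname(config$lc_scales[lc])
    dlon <- scale * stats::rt(k, config$nu)
    dlat <- scale * stats::rt(k, config$nu)
    gross <- stats::runif(k) < config$outlier_prob
    if (any(gross)) {
      m <- sum(gross)
      dlon[gross] <- dlon[gross] +
        sample(c(-1, 1), m, TRUE) * stats::runif(m, 0.6, 1) * config$outlier_deg
      dlat[gross] <- dlat[gross] +
        sample(c(-1, 1), m, TRUE) * stats::runif(m, 0.6, 1) * config$outlier_deg
    }
    rows[[i]] <- data.frame(
      animal_id = animal_id,
      timestamp = as.POSIXct(true_path$date[i], tz = "UTC") + secs,
      lon = wrap_lon(true_path$lon[i] + dlon),
      lat = pmin(pmax(true_path$lat[i] + dlat, -89.9), 89.9),
      lc = lc
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate isotope measurements for a cohort
#'
#' Each individual draws a true delta13C from its strategy's mixture
#' component and a true delta15N from the common unimodal distribution;
#' every physical sample adds replicate measurement noise. A configured
#' fraction of individuals is sampled twice, exercising replicate QC and
#' per-individual aggregation. Values are clipped to the configured delta15N
#' range. Randomness comes from the session RNG.
#'
#' @param truth Data frame with `individual_id`, `species`, `strategy`.
#' @param config A [synthetic_config()].
#' @return Measurement data frame (`sample_id`, `individual_id`, `species`,
#'   `d13C`, `d15N`, `cn_ratio`, `replicate_of`).
#' @export
simulate_isotopes <- function(truth, config = synthetic_config()) {
  n <- nrow(truth)
  mu13 <- ifelse(truth$strategy == "coastal",
                 config$d13c_coastal, config$d13c_oceanic)
  true13 <- stats::rnorm(n, mu13, config$d13c_sd)
  true15 <- pmin(pmax(stats::rnorm(n, config$d15n_mean, config$d15n_sd),
                      config$d15n_range[1]), config$d15n_range[2])
  dup <- stats::runif(n) < config$duplicate_rate
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- if (dup[i]) 2L else 1L
    sid <- paste0(truth$individual_id[i], "-s", seq_len(k))
    rows[[i]] <- data.frame(
      sample_id = sid,
      individual_id = truth$individual_id[i],
      species = truth$species[i],
      d13C = true13[i] + stats::rnorm(k, 0, config$rep_sd[["d13C"]]),
      d15N = pmin(pmax(true15[i] + stats::rnorm(k, 0, config$rep_sd[["d15N"]]),
                       config$d15n_range[1]), config$d15n_range[2]),
      cn_ratio = NA_real_,
      replicate_of = c(NA_character_, rep(sid[1], k - 1L))
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic study
#'
#' Produces everything the pipeline consumes — noisy Argos tracks for the
#' tracked cohort, isotope samples for everyone, region polygons and
#' bathymetry — together with the generating truth, which downstream code
#' must never consume (it exists for recovery tests).
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; the study is bit-reproducible given
#'   `(config, seed)`.
#' @return List of class `synthetic_study`: `tracks`, `true_paths` (named
#'   list), `isotopes`, `truth` (data frame `individual_id`, `species`,
#'   `tracked`, `strategy`, `region`), `regions`, `bathymetry`, `config`.
#' @export
simulate_study <- function(config = synthetic_config(), seed = 1) {
  set.seed(seed)
  geo <- make_regions_and_bathymetry(config)

  n_c <- round(config$true_coastal_fraction * config$n_tracked)
  tracked_strat <- sample(c(rep("coastal", n_c),
                            rep("oceanic", config$n_tracked - n_c)))
  n_cu <- round(config$true_coastal_fraction * config$n_untracked)
  untracked_strat <- sample(c(rep("coastal", n_cu),
                              rep("oceanic", config$n_untracked - n_cu)))

  truth <- data.frame(
    individual_id = c(sprintf("SAT%02d", seq_len(config$n_tracked)),
                      sprintf("UNT%03d", seq_len(config$n_untracked))),
    species = "leatherback",
    tracked = rep(c(TRUE, FALSE), c(config$n_tracked, config$n_untracked)),
    strategy = c(tracked_strat, untracked_strat),
    region = NA_character_
  )

  true_paths <- list()
  tracks <- vector("list", config$n_tracked)
  for (i in seq_len(config$n_tracked)) {
    id <- truth$individual_id[i]
    tp <- simulate_turtle_track(truth$strategy[i], config)
    truth$region[i] <- attr(tp, "region")
    true_paths[[id]] <- tp
    tracks[[i]] <- add_argos_noise(tp, config, animal_id = id)
  }
  tracks <- do.call(rbind, tracks)
  rownames(tracks) <- NULL

  isotopes <- simulate_isotopes(truth, config)

  structure(list(tracks = tracks, true_paths = true_paths,
                 isotopes = isotopes, truth = truth,
                 regions = geo$regions, bathymetry = geo$bathymetry,
                 config = config, seed = seed),
            class = "synthetic_study")
}

#' Write or read a synthetic study bundle on disk
#'
#' Serialises the pipeline inputs as the plain-text interchange formats the
#' readers expect (`tracks.csv`, `isotopes.csv`, `regions.geojson`,
#' `bathymetry.csv`) plus the generating `truth.json`.
#'
#' @param study A `synthetic_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `write_study_bundle()` returns `dir` invisibly;
#'   `read_study_bundle()` returns a list with `tracks`, `isotopes`,
#'   `regions`, `bathymetry`, `truth`.
#' @export
write_study_bundle <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tracks(study$tracks, file.path(dir, "tracks.csv"))
  write_isotopes(study$isotopes, file.path(dir, "isotopes.csv"))
  write_regions(study$regions, file.path(dir, "regions.geojson"))
  write_env_grid(study$bathymetry, file.path(dir, "bathymetry.csv"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_study_bundle
#' @export
read_study_bundle <- function(dir) {
  list(tracks = read_tracks(file.path(dir, "tracks.csv")),
       isotopes = read_isotopes(file.path(dir, "isotopes.csv")),
       regions = read_regions(file.path(dir, "regions.geojson")),
       bathymetry = read_env_grid(file.path(dir, "bathymetry.csv"),
                                  name = "bathymetry"),
       truth = jsonlite::fromJSON(file.path(dir, "truth.json")))
}
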