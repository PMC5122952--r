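test_that("great-circle distance matches closed-form and reference values", {
  expect_identical(great_circle_distance(12.3, -45.6, 12.3, -45.6), 0)
  # antipodal along the equator: half circumference
  expect_equal(great_circle_distance(0, 0, -180, 0), pi * 6371, tolerance = 1e-10)
  # quarter great circle
  expect_equal(great_circle_distance(0, 0, 90, 0), pi * 6371 / 2, tolerance = 1e-10)
  # symmetric
  expect_equal(great_circle_distance(10, 20, 30, -40),
               great_circle_distance(30, -40, 10, 20))
  # agrees with geosphere's haversine on the same radius
  set.seed(1)
  lon <- runif(20, -180, 179); lat <- runif(20, -80, 80)
  expect_equal(great_circle_distance(lon[1:10], lat[1:10], lon[11:20], lat[11:20]),
               geosphere::distHaversine(cbind(lon[1:10], lat[1:10]),
                                        cbind(lon[11:20], lat[11:20]),
                                        r = 6371000) / 1000,
               tolerance = 1e-9)
  expect_error(great_circle_distance(0, 95, 0, 0), "latitude")
})

test_that("great-circle distance satisfies the triangle inequality", {
  set.seed(42)
  for (i in 1:50) {
    lon <- runif(3, -180, 179); lat <- runif(3, -89, 89)
    ab <- great_circle_distance(lon[1], lat[1], lon[2], lat[2])
    bc <- great_circle_distance(lon[2], lat[2], lon[3], lat[3])
    ac <- great_circle_distance(lon[1], lat[1], lon[3], lat[3])
    expect_lte(ac, ab + bc + 1e-6)
  }
})

test_that("speed filter drops only violating fixes and is idempotent", {
  # two fixes 100 km / 24 h apart: both retained
  tr <- make_track(c("2012-01-01 00:00:00", "2012-01-02 00:00:00"),
                   lon = c(35, 35), lat = c(-28, -28 + 100 / 111.19493))
  expect_equal(nrow(speed_filter(tr)), 2)

  # A->B 500 km in 1 d violates; A->C 100 km in 2 d is fine: B removed, C kept
  tr <- make_track(c("2012-01-01 00:00:00", "2012-01-02 00:00:00",
                     "2012-01-03 00:00:00"),
                   lon = c(35, 35, 35),
                   lat = -28 + c(0, 500, 100) / 111.19493)
  out <- speed_filter(tr)
  expect_equal(nrow(out), 2)
  expect_equal(out$lat, tr$lat[c(1, 3)])

  # compliant track unchanged; filtering twice changes nothing
  tr <- make_track(sprintf("2012-01-%02d 00:00:00", 1:10),
                   lon = rep(35, 10), lat = -28 + (0:9) * 0.5)
  expect_identical(speed_filter(tr), tr)
  set.seed(7)
  noisy <- make_track(sprintf("2012-01-%02d %02d:00:00", rep(1:15, each = 2),
                              rep(c(3, 15), 15)),
                      lon = 35 + cumsum(rnorm(30, 0, 0.8)),
                      lat = -28 + cumsum(rnorm(30, 0, 0.8)))
  once <- speed_filter(noisy)
  expect_identical(speed_filter(once), once)
  # no retained consecutive pair exceeds vmax
  sp <- great_circle_distance(head(once$lon, -1), head(once$lat, -1),
                              once$lon[-1], once$lat[-1]) /
    as.numeric(diff(once$timestamp), units = "days")
  expect_true(all(sp <= 240 + 1e-9))
  # first fix always retained
  expect_identical(once[1, ], noisy[1, ])
})

test_that("best daily fix keeps the top location class, earliest on ties", {
  tr <- make_track(c("2012-01-01 10:00:00", "2012-01-01 04:00:00"),
                   lon = c(35, 36), lat = c(-28, -27), lc = c("3", "B"))
  out <- best_daily_fix(tr)
  expect_equal(nrow(out), 1)
  expect_equal(out$lc, "3")

  tr <- make_track(c("2012-01-01 02:00:00", "2012-01-01 14:00:00"),
                   lon = c(35, 36), lat = c(-28, -27), lc = "1")
  out <- best_daily_fix(tr)
  expect_equal(format(out$timestamp, "%H"), "02")

  tr <- make_track(c("2012-01-01 12:00:00", "2012-01-02 12:00:00",
                     "2012-01-03 12:00:00"),
                   lon = 35:37, lat = c(-28, -27, -26), lc = c("B", "A", "0"))
  expect_equal(nrow(best_daily_fix(tr)), 3)
})

test_that("best daily fix output is a per-day-unique subsequence of its input", {
  set.seed(11)
  n <- 60
  tr <- make_track(utc("2012-01-01") + sort(runif(n, 0, 15 * 86400)),
                   lon = runif(n, 30, 40), lat = runif(n, -30, -20),
                   lc = sample(LC_LEVELS, n, TRUE))
  tr$timestamp <- utc("2012-01-01") + sort(round(runif(n, 0, 15 * 86400)))
  out <- best_daily_fix(tr)
  expect_lte(max(table(as.Date(out$timestamp, tz = "UTC"))), 1)
  key_in <- paste(tr$timestamp, tr$lon, tr$lat)
  key_out <- paste(out$timestamp, out$lon, out$lat)
  expect_true(all(key_out %in% key_in))
  expect_false(is.unsorted(match(key_out, key_in)))
})

test_that("daily speeds divide displacement by elapsed days", {
  path <- data.frame(date = as.Date("2012-01-01") + c(0, 2),
                     lon = c(35, 35), lat = c(-28, -28 + 10 / 111.19493))
  sp <- daily_speeds(path)
  expect_equal(sp$speed, 5, tolerance = 1e-6)
  expect_equal(sp$dt_days, 2)

  stationary <- data.frame(date = as.Date("2012-01-01") + 0:5,
                           lon = rep(35, 6), lat = rep(-28, 6))
  expect_equal(daily_speeds(stationary)$speed, rep(0, 5))

  transit <- make_daily_path(20, speed_kmd = 50)
  expect_equal(daily_speeds(transit)$speed, rep(50, 19), tolerance = 1e-6)

  expect_error(daily_speeds(transit[1, ]), "two positions")
})

test_that("residence detection honours speed and duration thresholds", {
  seg <- detect_residence(rep(3, 20))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$mode, "residence")
  expect_equal(seg$n_days, 20)
  expect_equal(seg$mean_speed, 3)

  expect_equal(detect_residence(rep(50, 30))$mode, "transit")

  # a 10-day slow spell (eddy loiter) stays transit under min_days = 15
  sp <- c(rep(40, 10), rep(3, 10), rep(40, 10))
  seg <- detect_residence(sp, min_days = 15)
  expect_true(all(seg$mode == "transit"))
  expect_equal(nrow(seg), 1)  # merged into one transit segment

  # mixed series: long slow run becomes residence with correct bounds
  dates <- as.Date("2012-01-01") + 0:40
  sp <- c(rep(40, 10), rep(2, 20), rep(40, 10))
  seg <- detect_residence(sp, dates = dates)
  expect_equal(seg$mode, c("transit", "residence", "transit"))
  expect_equal(seg$start_day[2], dates[11])
  expect_equal(seg$end_day[2], dates[31])

  # duration counts days, not legs: 8 slow legs over 16 days qualify
  seg <- detect_residence(rep(2, 8), dt_days = 2)
  expect_equal(seg$mode, "residence")
  expect_error(detect_residence(rep(2, 5), v_res = -1), "non-negative")
})

test_that("grid sampling is nearest-node and rejects out-of-domain points", {
  g <- env_grid(lon = seq(30, 40, 1), lat = seq(-30, -20, 1),
                values = outer(seq(30, 40, 1), seq(-30, -20, 1), `+`))
  expect_equal(sample_grid(g, 35, -25), 10)
  expect_equal(sample_grid(g, 35.4, -25.4), 10)  # nearest node still (35,-25)
  expect_equal(sample_grid(g, 35.6, -24.4), 36 - 24)
  expect_error(sample_grid(g, 50, -25), "outside")
  expect_error(env_grid(c(1, 1, 2), 1:3, matrix(0, 3, 3)), "increasing")
})

test_that("strategy classification separates shelf residence from oceanic tracks", {
  geo <- make_regions_and_bathymetry()
  # 30-day residence in the shallow strip after a short run north
  res_path <- rbind(make_daily_path(10, speed_kmd = 50, start = c(35, -28)),
                    within(make_daily_path(30, speed_kmd = 0,
                                           start = c(35, -23.5),
                                           start_date = as.Date("2012-01-11")),
                           lat <- lat + cumsum(rep(0.001, 30))))
  lab <- classify_strategy(res_path, geo$regions, geo$bathymetry)
  expect_equal(lab$strategy, "coastal")
  expect_equal(lab$region, "MC")

  # sustained southeastward transit ending in the deep WIO
  oce_path <- make_daily_path(60, speed_kmd = 45, start = c(40, -40))
  oce_path$lon <- seq(40, 70, length.out = 60)
  lab <- classify_strategy(oce_path, geo$regions, geo$bathymetry)
  expect_equal(lab$strategy, "oceanic")
  expect_equal(lab$region, "WIO")

  # a 10-day deep-water loiter is eddy behaviour, not coastal residence
  loiter <- rbind(make_daily_path(20, speed_kmd = 45, start = c(45, -35)),
                  make_daily_path(10, speed_kmd = 1,
                                  start = c(45, -35 + 19 * 45 / 111.19493),
                                  start_date = as.Date("2012-01-21")),
                  make_daily_path(20, speed_kmd = 45,
                                  start = c(45, -35 + 19 * 45 / 111.19493 + 9 / 111.19493),
                                  start_date = as.Date("2012-01-31")))
  loiter$date <- as.Date("2012-01-01") + seq_len(nrow(loiter)) - 1
  lab <- classify_strategy(loiter, geo$regions, geo$bathymetry)
  expect_equal(lab$strategy, "oceanic")

  expect_error(classify_strategy(res_path, NULL, geo$bathymetry), "required")
})

test_that("track CSV round-trips and rejects malformed rows", {
  tr <- make_track(c("2012-01-01 03:00:00", "2012-01-02 14:30:00",
                     "2012-01-04 23:59:59"),
                   lon = c(35.123, 35.456, 36.001),
                   lat = c(-28.5, -28.1, -27.9), lc = c("3", "A", "0"))
  f <- tempfile(fileext = ".csv")
  write_tracks(tr, f)
  back <- read_tracks(f)
  expect_equal(back, tr)

  # Z-class fixes never survive ingestion
  trz <- tr; trz$lc[2] <- "Z"
  write_tracks(trz, f)
  expect_equal(read_tracks(f)$lc, c("3", "0"))

  # unknown class rejected with its row number
  writeLines(c("animal_id,timestamp,lat,lon,lc",
               "T1,2012-01-01T00:00:00,-28,35,3",
               "T1,2012-01-02T00:00:00,-28,35,X"), f)
  expect_error(read_tracks(f), "row 2.*location class")
  writeLines(c("animal_id,timestamp,lat,lon,lc",
               "T1,01/02/2012,-28,35,3"), f)
  expect_error(read_tracks(f), "ISO-8601")
  writeLines("animal_id,timestamp,lat,lon,lc", f)
  expect_equal(nrow(read_tracks(f)), 0)
})
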