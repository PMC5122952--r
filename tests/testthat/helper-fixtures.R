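# small fixtures shared across test files; everything built in code

utc <- function(x) as.POSIXct(x, tz = "UTC")

# a minimal track data frame
make_track <- function(times, lon, lat, lc = "3", id = "T1") {
  data.frame(animal_id = id, timestamp = utc(times),
             lon = lon, lat = lat, lc = rep_len(lc, length(lon)),
             stringsAsFactors = FALSE)
}

# daily path (date/lon/lat) travelling at constant speed due north
make_daily_path <- function(n, speed_kmd = 50, start = c(35, -28),
                            start_date = as.Date("2012-01-01")) {
  lat_step <- speed_kmd / 111.19493  # km per degree latitude on R = 6371 sphere
  data.frame(date = start_date + seq_len(n) - 1,
             lon = rep(start[1], n),
             lat = start[2] + (seq_len(n) - 1) * lat_step)
}

# noise-free all-class-3, one-fix-per-day observation settings
noise_free_config <- function(...) {
  cfg <- synthetic_config(...)
  cfg$lc_freq <- c("3" = 1, "2" = 0, "1" = 0, "0" = 0, "A" = 0, "B" = 0)
  cfg$fixes_per_day_probs <- c(0, 1, 0, 0)
  cfg$outlier_prob <- 0
  cfg$lc_scales <- argos_lc_scales() * 0
  cfg
}

# convert a true daily path into a one-fix-per-day track at given tau (deg)
observe_daily <- function(true_path, tau = 0.02, id = "A1") {
  cfg <- noise_free_config()
  cfg$lc_scales <- argos_lc_scales() * (tau / argos_lc_scales()[["3"]])
  add_argos_noise(true_path, cfg, animal_id = id)
}

reduced_ssm <- function(...) ssm_config(n_iter = 3000, burn_in = 1000, ...)
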