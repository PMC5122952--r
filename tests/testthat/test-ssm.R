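test_that("DCRW simulation follows the persistence/rotation algebra", {
  set.seed(1)
  # gamma = 0, sigma -> 0: stays at the start
  p <- simulate_dcrw(10, gamma = 0, sigma = 1e-12, start = c(35, -28))
  expect_equal(p$lon, rep(35, 10), tolerance = 1e-9)
  expect_equal(p$lat, rep(-28, 10), tolerance = 1e-9)

  # pure persistence: straight line with constant step
  p <- simulate_dcrw(10, gamma = 1, theta = 0, sigma = 1e-12,
                     first_step = c(0.3, -0.1))
  expect_equal(diff(p$lon), rep(0.3, 9), tolerance = 1e-6)
  expect_equal(diff(p$lat), rep(-0.1, 9), tolerance = 1e-6)

  # quarter-turn rotation: displacements orbit a 4-step square
  p <- simulate_dcrw(9, gamma = 1, theta = pi / 2, sigma = 1e-12,
                     start = c(0, 0), first_step = c(0.1, 0))
  d <- cbind(diff(p$lon), diff(p$lat))
  expect_equal(d[1:4, ], rbind(c(0.1, 0), c(0, 0.1), c(-0.1, 0), c(0, -0.1)),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(unlist(p[5, c("lon", "lat")]), c(lon = 0, lat = 0),
               tolerance = 1e-6)
  expect_error(simulate_dcrw(1), "n_days")
})

test_that("DCRW log posterior matches hand-computed closed forms", {
  cfg <- ssm_config()
  # straight-line path with zero innovations under gamma = 1, theta = 0
  n <- 12
  path <- cbind(seq(35, by = 0.2, length.out = n),
                seq(-28, by = 0.1, length.out = n))
  params <- list(gamma = 1, theta = 0, sigma = 0.1, tau = 0.05)
  obs0 <- data.frame(day = integer(), lon = numeric(), lat = numeric(),
                     mult = numeric())

  # observation exactly at the latent position: term equals the t-density at 0
  obs <- data.frame(day = 3L, lon = path[3, 1], lat = path[3, 2], mult = 2)
  lp_with <- dcrw_log_posterior(path, params, obs, cfg)
  lp_without <- dcrw_log_posterior(path, params, obs0, cfg)
  sc <- params$tau * 2
  expect_equal(lp_with - lp_without, 2 * (dt(0, cfg$nu, log = TRUE) - log(sc)),
               tolerance = 1e-12)

  # doubling sigma on a zero-innovation path: process term changes by
  # -2 ln 2 per step (two coordinates), plus the sigma prior difference
  p2 <- params; p2$sigma <- 0.2
  delta <- dcrw_log_posterior(path, p2, obs0, cfg) -
    dcrw_log_posterior(path, params, obs0, cfg)
  prior_delta <- dnorm(0.2, 0, cfg$sigma_hn, log = TRUE) -
    dnorm(0.1, 0, cfg$sigma_hn, log = TRUE)
  expect_equal(delta, -(n - 2) * 2 * log(2) + prior_delta, tolerance = 1e-10)

  # outside the uniform prior support
  expect_identical(dcrw_log_posterior(path, list(gamma = 1.2, theta = 0,
                                                 sigma = 0.1, tau = 0.05),
                                      obs0, cfg), -Inf)
  expect_error(dcrw_log_posterior(path * NA, params, obs0, cfg), "non-finite")
})

test_that("Gelman-Rubin matches direct arithmetic and flags separation", {
  set.seed(3)
  chains <- list(rnorm(40), rnorm(40), rnorm(40))
  # longhand formula
  n <- 40
  W <- mean(sapply(chains, var))
  B <- n * var(sapply(chains, mean))
  expect_equal(gelman_rubin(chains), sqrt(((n - 1) / n * W + B / n) / W),
               tolerance = 1e-12)

  x <- rnorm(100)
  expect_equal(gelman_rubin(list(x, x)), sqrt(99 / 100), tolerance = 1e-12)

  sep <- list(rnorm(100, 0, 1), rnorm(100, 50, 1))
  expect_gt(gelman_rubin(sep), 10)
  expect_error(gelman_rubin(list(rnorm(10))), "2 chains")
})

test_that("SSM sample bookkeeping is exact", {
  set.seed(5)
  p <- simulate_dcrw(20, gamma = 0.6, sigma = 0.1, start = c(40, -30),
                     first_step = c(0.1, 0))
  tp <- data.frame(date = as.Date("2012-01-01") + p$day - 1,
                   lon = p$lon, lat = p$lat)
  tr <- observe_daily(tp, tau = 0.02)
  cfg <- ssm_config(n_iter = 900, burn_in = 300, thin = 3)
  fit <- suppressWarnings(fit_ssm(tr, cfg))
  expect_equal(fit$n_samples, 2 * (900 - 300) / 3)
  for (ch in fit$chains) {
    expect_equal(nrow(ch$lon), 200)
    expect_equal(length(ch$gamma), 200)
    expect_equal(ncol(ch$lat), length(fit$dates))
  }
  expect_error(fit_ssm(tr[1:3, ], cfg), "at least 5")
})

test_that("SSM tracks near-noiseless daily observations closely", {
  set.seed(8)
  p <- simulate_dcrw(30, gamma = 0.6, theta = 0, sigma = 0.12,
                     start = c(40, -30), first_step = c(0.15, 0))
  tp <- data.frame(date = as.Date("2012-01-01") + p$day - 1,
                   lon = p$lon, lat = p$lat)
  tr <- observe_daily(tp, tau = 0.002)
  fit <- suppressWarnings(fit_ssm(tr, reduced_ssm(tau_hn = 0.005)))
  mp <- ssm_point_path(fit)
  expect_lt(max(abs(mp$lon - tr$lon)), 0.05)
  expect_lt(max(abs(mp$lat - tr$lat)), 0.05)
})

test_that("with persistence pinned at zero, gap days track linear interpolation", {
  set.seed(9)
  # steady 0.2 deg/day drift with a 3-day gap between days 6 and 10
  days <- c(1:6, 10:14)
  tp <- data.frame(date = as.Date("2012-01-01") + days - 1,
                   lon = 35 + 0.2 * (days - 1), lat = -28 + 0.1 * (days - 1))
  tr <- observe_daily(tp, tau = 0.01)
  cfg <- reduced_ssm(gamma_range = c(0, 1e-6))
  fit <- suppressWarnings(fit_ssm(tr, cfg))
  merged <- merge_daily(tr, fit)
  gap <- merged[merged$source == "modelled", ]
  expect_equal(nrow(gap), 3)
  interp_lon <- 35 + 0.2 * (7:9 - 1)
  interp_lat <- -28 + 0.1 * (7:9 - 1)
  expect_true(all(gap$lon_lo <= interp_lon & interp_lon <= gap$lon_hi))
  expect_true(all(gap$lat_lo <= interp_lat & interp_lat <= gap$lat_hi))
  # modelled point estimate equals the mean of that day's pooled samples
  j <- match(gap$date[1], fit$dates)
  pooled <- do.call(rbind, lapply(fit$chains, function(ch) ch$lon[, j, drop = FALSE]))
  expect_equal(gap$lon[1], mean(pooled), tolerance = 1e-12)
})

test_that("chains from different starts converge on a well-identified track", {
  set.seed(10)
  p <- simulate_dcrw(40, gamma = 0.7, theta = 0, sigma = 0.15,
                     start = c(40, -30), first_step = c(0.2, 0.05))
  tp <- data.frame(date = as.Date("2012-01-01") + p$day - 1,
                   lon = p$lon, lat = p$lat)
  tr <- observe_daily(tp, tau = 0.02)
  # scale parameters mix more slowly than positions at this length; the
  # check here is convergence of the daily positions themselves
  fit <- suppressWarnings(fit_ssm(tr, ssm_config(n_iter = 5000, burn_in = 2000)))
  expect_true(all(fit$rhat$lon <= 1.1))
  expect_true(all(fit$rhat$lat <= 1.1))
})

test_that("merging prefers raw fixes and reports the modelled fraction", {
  set.seed(12)
  days <- c(1:8, 10)
  tp <- data.frame(date = as.Date("2012-01-01") + days - 1,
                   lon = 35 + 0.1 * days, lat = -28 + 0.05 * days)
  tr <- observe_daily(tp, tau = 0.02)
  fit <- suppressWarnings(fit_ssm(tr, reduced_ssm()))
  merged <- merge_daily(tr, fit)
  expect_equal(nrow(merged), 10)
  expect_equal(sum(merged$source == "modelled"), 1)
  expect_equal(attr(merged, "fraction_modelled"), 0.1)
  obs_rows <- merged[merged$source == "observed", ]
  # observed coordinates pass through bit-identically
  expect_identical(obs_rows$lon, tr$lon)
  expect_identical(obs_rows$lat, tr$lat)
  expect_true(all(is.na(obs_rows$lon_lo)))
  expect_true(all(!is.na(merged$lon_lo[merged$source == "modelled"])))

  # gap-free track: nothing modelled
  tp2 <- data.frame(date = as.Date("2012-01-01") + 0:9,
                    lon = 35 + 0.1 * (0:9), lat = rep(-28, 10))
  tr2 <- observe_daily(tp2, tau = 0.02)
  fit2 <- suppressWarnings(fit_ssm(tr2, reduced_ssm()))
  m2 <- merge_daily(tr2, fit2)
  expect_equal(attr(m2, "fraction_modelled"), 0)

  # span mismatch is an error
  expect_error(merge_daily(tr2[1:8, ], fit2), "span")
})
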