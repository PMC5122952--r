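#' State-space model configuration
#'
#' Settings for the Bayesian first-difference correlated-random-walk (DCRW)
#' model fitted by [fit_ssm()]. Defaults follow the full analysis protocol
#' (2 chains, 30000 iterations, 10000 burn-in, thinning 5); a reduced profile
#' such as `ssm_config(n_iter = 5000, burn_in = 2000)` is appropriate for
#' desk-scale runs and simulation studies.
#'
#' Priors: gamma (move persistence) uniform on `gamma_range`; theta (mean
#' turn angle, radians) uniform on `theta_range`; sigma (process standard
#' deviation, degrees per day per coordinate) and tau (observation scale for
#' a class-3 fix, degrees) half-Normal with scales `sigma_hn`, `tau_hn`.
#' Observation errors are Student-t with `nu` degrees of freedom and per-class
#' scale `tau * lc_scales[lc] / lc_scales["3"]`.
#'
#' @param n_iter MCMC iterations per chain.
#' @param burn_in Burn-in iterations discarded from each chain.
#' @param thin Thinning interval; `(n_iter - burn_in)` must be divisible by it.
#' @param n_chains Number of chains (at least 2, for convergence diagnostics).
#' @param nu Observation t-distribution degrees of freedom (> 2).
#' @param gamma_range,theta_range Uniform prior supports.
#' @param sigma_hn,tau_hn Half-Normal prior scales (degrees).
#' @param first_step_sd Standard deviation (degrees) of the vague Normal tying
#'   the second day's position to the first.
#' @param lc_scales Per-class error scales, see [argos_lc_scales()].
#' @param rhat_threshold Gelman-Rubin threshold above which [fit_ssm()] warns.
#' @return A list of class `ssm_config`.
#' @export
ssm_config <- function(n_iter = 30000, burn_in = 10000, thin = 5,
                       n_chains = 2, nu = 5,
                       gamma_range = c(0, 1), theta_range = c(-pi, pi),
                       sigma_hn = 0.3, tau_hn = 0.05,
                       first_step_sd = 0.5,
                       lc_scales = argos_lc_scales(),
                       rhat_threshold = 1.1) {
  stopifnot(burn_in < n_iter, thin >= 1, n_chains >= 2, nu > 2,
            sigma_hn > 0, tau_hn > 0, first_step_sd > 0)
  if ((n_iter - burn_in) %% thin != 0) {
    stop("(n_iter - burn_in) must be divisible by thin", call. = FALSE)
  }
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 n_chains = n_chains, nu = nu,
                 gamma_range = gamma_range, theta_range = theta_range,
                 sigma_hn = sigma_hn, tau_hn = tau_hn,
                 first_step_sd = first_step_sd, lc_scales = lc_scales,
                 rhat_threshold = rhat_threshold),
            class = "ssm_config")
}

#' Simulate a first-difference correlated random walk
#'
#' The movement process underlying [fit_ssm()]:
#' `x_t = x_{t-1} + gamma * T(theta) (x_{t-1} - x_{t-2}) + eps_t`, with
#' `eps_t ~ Normal(0, sigma^2)` per coordinate and `T(theta)` the 2-D
#' rotation matrix. Positions are in degrees lon/lat treated as planar over
#' the simulated extent.
#'
#' @param n_days Number of daily positions (>= 2).
#' @param gamma Move persistence in `[0, 1]`.
#' @param theta Mean turn angle, radians.
#' @param sigma Process standard deviation per coordinate, degrees.
#' @param start Starting position `c(lon, lat)`.
#' @param first_step Deterministic displacement seeding day 2 (degrees);
#'   process noise is added on top.
#' @return Data frame `day`, `lon`, `lat`.
#' @export
simulate_dcrw <- function(n_days, gamma = 0.7, theta = 0, sigma = 0.1,
                          start = c(0, 0), first_step = c(0, 0)) {
  if (n_days < 2) stop("n_days must be >= 2", call. = FALSE)
  stopifnot(gamma >= 0, gamma <= 1, sigma >= 0)
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  x <- matrix(NA_real_, n_days, 2)
  x[1, ] <- start
  x[2, ] <- x[1, ] + first_step + stats::rnorm(2, 0, sigma)
  if (n_days > 2) {
    for (t in 3:n_days) {
      d <- x[t - 1, ] - x[t - 2, ]
      x[t, ] <- x[t - 1, ] + gamma * as.vector(rot %*% d) +
        stats::rnorm(2, 0, sigma)
    }
  }
  data.frame(day = seq_len(n_days), lon = x[, 1], lat = x[, 2])
}

#' Log posterior density of the DCRW state-space model
#'
#' Sum of the process log-density over latent daily positions, the Student-t
#' observation log-density, and the parameter log-priors (see
#' [ssm_config()]). Exposed mainly for testing and diagnostics; [fit_ssm()]
#' samples from this same density.
#'
#' @param path Numeric matrix `n x 2` of latent daily positions (lon, lat).
#' @param params List with elements `gamma`, `theta`, `sigma`, `tau`.
#' @param obs Data frame with `day` (1-based index into `path` rows), `lon`,
#'   `lat`, and `mult` (per-fix scale multiplier, 1 for a class-3 fix).
#' @param config An [ssm_config()].
#' @return Scalar log density (`-Inf` outside the prior support).
#' @export
dcrw_log_posterior <- function(path, params, obs, config = ssm_config()) {
  path <- as.matrix(path)
  if (any(!is.finite(path))) stop("non-finite path", call. = FALSE)
  n <- nrow(path)
  g <- params$gamma; th <- params$theta; s <- params$sigma; tau <- params$tau
  if (g < config$gamma_range[1] || g > config$gamma_range[2] ||
      th < config$theta_range[1] || th > config$theta_range[2] ||
      s <= 0 || tau <= 0) {
    return(-Inf)
  }
  lp <- -log(diff(config$gamma_range)) - log(diff(config$theta_range)) +
    stats::dnorm(s, 0, config$sigma_hn, log = TRUE) + log(2) +
    stats::dnorm(tau, 0, config$tau_hn, log = TRUE) + log(2)
  if (n >= 2) {
    d1 <- path[2, ] - path[1, ]
    lp <- lp + sum(stats::dnorm(d1, 0, config$first_step_sd, log = TRUE))
  }
  if (n >= 3) {
    d <- diff(path)                       # (n-1) x 2 displacements
    prev <- d[-(n - 1), , drop = FALSE]
    pred <- g * cbind(cos(th) * prev[, 1] - sin(th) * prev[, 2],
                      sin(th) * prev[, 1] + cos(th) * prev[, 2])
    resid <- d[-1, , drop = FALSE] - pred
    lp <- lp + sum(stats::dnorm(resid, 0, s, log = TRUE))
  }
  if (nrow(obs) > 0) {
    sc <- tau * obs$mult
    zx <- (obs$lon - path[obs$day, 1]) / sc
    zy <- (obs$lat - path[obs$day, 2]) / sc
    lp <- lp + sum(stats::dt(zx, config$nu, log = TRUE) - log(sc)) +
      sum(stats::dt(zy, config$nu, log = TRUE) - log(sc))
  }
  lp
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Standard split-free R-hat over parallel chains:
#' `sqrt(((n-1)/n * W + B/n) / W)` with `W` the mean within-chain variance
#' and `B` the between-chain variance of chain means times `n`.
#'
#' @param chains List of equal-length numeric vectors (one per chain), or a
#'   matrix with one column per chain.
#' @return Scalar R-hat.
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  m <- length(chains)
  if (m < 2) stop("need at least 2 chains", call. = FALSE)
  n <- unique(lengths(chains))
  if (length(n) != 1 || n < 2) stop("chains must have equal length >= 2", call. = FALSE)
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the DCRW state-space model to a filtered track
#'
#' Metropolis-within-Gibbs sampling of daily latent positions and the DCRW
#' parameters (gamma, theta, sigma, tau), with per-site and per-parameter
#' random-walk proposals adapted during burn-in. Chains start from
#' over-dispersed initial values around the linearly interpolated fixes.
#' Reproducible under `set.seed()`. Convergence is summarised by
#' Gelman-Rubin R-hat on the four parameters and on every daily coordinate;
#' parameter R-hat above the configured threshold raises a warning but the
#' samples are still returned.
#'
#' @param track Track data frame for one animal, speed-filtered, at most one
#'   fix per day (apply [speed_filter()] and [best_daily_fix()] first);
#'   at least 5 fixes.
#' @param config An [ssm_config()].
#' @return An object of class `ssm_posterior`: `dates` (daily grid from first
#'   to last fix day), `chains` (per-chain lists of `lon`/`lat` sample
#'   matrices and parameter vectors), `rhat` (named parameter vector plus
#'   per-day `lon`/`lat` vectors), `n_samples`, `obs` and `config`.
#' @export
fit_ssm <- function(track, config = ssm_config()) {
  stopifnot(inherits(config, "ssm_config"))
  if (length(unique(track$animal_id)) > 1) {
    stop("fit_ssm takes a single animal's track", call. = FALSE)
  }
  if (nrow(track) < 5) stop("need at least 5 retained fixes", call. = FALSE)
  day <- as.Date(track$timestamp, tz = "UTC")
  if (anyDuplicated(day)) {
    stop("track must have at most one fix per day (use best_daily_fix)",
         call. = FALSE)
  }
  dates <- seq(min(day), max(day), by = "day")
  n <- length(dates)
  mult_tab <- config$lc_scales / config$lc_scales[["3"]]
  obs <- data.frame(day = as.integer(day - min(day)) + 1L,
                    lon = track$lon, lat = track$lat,
                    mult = unname(mult_tab[track$lc]))

  base_lon <- stats::approx(obs$day, obs$lon, xout = seq_len(n), rule = 2)$y
  base_lat <- stats::approx(obs$day, obs$lat, xout = seq_len(n), rule = 2)$y

  clamp <- function(x, r) pmin(pmax(x, r[1] + 1e-9), r[2] - 1e-9)
  chains <- vector("list", config$n_chains)
  for (k in seq_len(config$n_chains)) {
    jit <- 0.02 * k
    x0 <- cbind(base_lon + stats::rnorm(n, 0, jit),
                base_lat + stats::rnorm(n, 0, jit))
    gamma0 <- clamp(stats::runif(1, 0.1, 0.9), config$gamma_range)
    theta0 <- clamp(stats::rnorm(1, 0, 0.2), config$theta_range)
    sigma0 <- stats::runif(1, 0.3, 1.5) * config$sigma_hn
    tau0 <- stats::runif(1, 0.3, 1.5) * config$tau_hn
    chains[[k]] <- dcrw_chain_cpp(
      x0, obs$day, obs$lon, obs$lat, obs$mult,
      gamma0, theta0, sigma0, tau0,
      config$n_iter, config$burn_in, config$thin,
      config$gamma_range[1], config$gamma_range[2],
      config$theta_range[1], config$theta_range[2],
      config$sigma_hn, config$tau_hn, config$nu, config$first_step_sd
    )
  }

  par_rhat <- vapply(c("gamma", "theta", "sigma", "tau"), function(p) {
    gelman_rubin(lapply(chains, `[[`, p))
  }, numeric(1))
  lon_rhat <- vapply(seq_len(n), function(j) {
    gelman_rubin(lapply(chains, function(ch) ch$lon[, j]))
  }, numeric(1))
  lat_rhat <- vapply(seq_len(n), function(j) {
    gelman_rubin(lapply(chains, function(ch) ch$lat[, j]))
  }, numeric(1))
  if (any(par_rhat > config$rhat_threshold)) {
    warning("SSM convergence: parameter R-hat above ",
            config$rhat_threshold, " (",
            paste(sprintf("%s=%.3f", names(par_rhat), par_rhat), collapse = ", "),
            ")", call. = FALSE)
  }

  structure(list(
    dates = dates,
    chains = chains,
    rhat = list(params = par_rhat, lon = lon_rhat, lat = lat_rhat),
    n_samples = config$n_chains * (config$n_iter - config$burn_in) / config$thin,
    obs = obs,
    config = config
  ), class = "ssm_posterior")
}

#' @export
print.ssm_posterior <- function(x, ...) {
  cat(sprintf("<ssm_posterior: %d days, %d samples (%d chains), max param R-hat %.3f>\n",
              length(x$dates), x$n_samples, length(x$chains),
              max(x$rhat$params)))
  invisible(x)
}

pooled_samples <- function(posterior, what) {
  do.call(rbind, lapply(posterior$chains, `[[`, what))
}

#' Posterior mean daily path
#'
#' Pooled posterior means of every day's latent position — the smoothed path
#' used for behavioural metrics (speeds, residence detection).
#'
#' @param posterior An `ssm_posterior` from [fit_ssm()].
#' @return Data frame `date`, `lon`, `lat`.
#' @export
ssm_point_path <- function(posterior) {
  stopifnot(inherits(posterior, "ssm_posterior"))
  data.frame(date = posterior$dates,
             lon = colMeans(pooled_samples(posterior, "lon")),
             lat = colMeans(pooled_samples(posterior, "lat")))
}

#' Posterior credible interval for a parameter
#'
#' @param posterior An `ssm_posterior`.
#' @param param One of `"gamma"`, `"theta"`, `"sigma"`, `"tau"`.
#' @param level Credible level, default 0.95.
#' @return Named vector `lo`, `hi`.
#' @export
ssm_param_ci <- function(posterior, param = "gamma", level = 0.95) {
  s <- unlist(lapply(posterior$chains, `[[`, param))
  q <- stats::quantile(s, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  c(lo = q[1], hi = q[2])
}

#' Merge observed fixes with modelled daily positions
#'
#' Builds the final daily path: days with a retained fix carry that fix
#' verbatim (source `"observed"`, raw data preferred over the model); days
#' without one take the posterior mean with a 95% credible interval (source
#' `"modelled"`). The fraction of modelled days is attached as attribute
#' `fraction_modelled`.
#'
#' @param track The same filtered one-fix-per-day track passed to [fit_ssm()].
#' @param posterior The fitted `ssm_posterior`; its day span must match the
#'   track's.
#' @return Data frame `date, lon, lat, source, lon_lo, lon_hi, lat_lo,
#'   lat_hi` with one row per day.
#' @export
merge_daily <- function(track, posterior) {
  stopifnot(inherits(posterior, "ssm_posterior"))
  day <- as.Date(track$timestamp, tz = "UTC")
  if (min(day) != min(posterior$dates) || max(day) != max(posterior$dates)) {
    stop("posterior day span does not match track", call. = FALSE)
  }
  lon_s <- pooled_samples(posterior, "lon")
  lat_s <- pooled_samples(posterior, "lat")
  dates <- posterior$dates
  idx <- match(dates, day)
  observed <- !is.na(idx)
  out <- data.frame(
    date = dates,
    lon = ifelse(observed, track$lon[idx], colMeans(lon_s)),
    lat = ifelse(observed, track$lat[idx], colMeans(lat_s)),
    source = ifelse(observed, "observed", "modelled"),
    lon_lo = NA_real_, lon_hi = NA_real_,
    lat_lo = NA_real_, lat_hi = NA_real_
  )
  if (any(!observed)) {
    j <- which(!observed)
    out$lon_lo[j] <- apply(lon_s[, j, drop = FALSE], 2, stats::quantile, 0.025)
    out$lon_hi[j] <- apply(lon_s[, j, drop = FALSE], 2, stats::quantile, 0.975)
    out$lat_lo[j] <- apply(lat_s[, j, drop = FALSE], 2, stats::quantile, 0.025)
    out$lat_hi[j] <- apply(lat_s[, j, drop = FALSE], 2, stats::quantile, 0.975)
  }
  attr(out, "fraction_modelled") <- mean(!observed)
  out
}

#' Read and write daily paths
#'
#' CSV schema: `animal_id,date,lat,lon,source,lat_lo,lat_hi,lon_lo,lon_hi`.
#'
#' @param paths Daily-path data frame (with an `animal_id` column).
#' @param path File path.
#' @return `read_daily_paths()` returns the data frame; `write_daily_paths()`
#'   returns `path` invisibly.
#' @export
write_daily_paths <- function(paths, path) {
  cols <- c("animal_id", "date", "lat", "lon", "source",
            "lat_lo", "lat_hi", "lon_lo", "lon_hi")
  utils::write.csv(paths[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_daily_paths
#' @export
read_daily_paths <- function(path) {
  df <- utils::read.csv(path)
  df$date <- as.Date(df$date)
  df
}
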