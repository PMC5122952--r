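#' Pipeline configuration
#'
#' Houses the analysis constants: the 240 km per day maximum-speed filter,
#' the 5 km per day residence threshold, the 15-day minimum residence
#' duration, the 50 m isobath bounding coastal habitat, the strict > 0.80
#' assignment threshold, and the 0.05 alpha level, together with the
#' state-space model settings.
#'
#' @param vmax Maximum plausible speed for the Argos filter, km per day.
#' @param v_res Residence speed threshold, km per day.
#' @param min_residence_days Minimum residence duration, days.
#' @param isobath_m Coastal depth contour, metres (negative below sea level).
#' @param shallow_frac Fraction of residence positions that must be shallow
#'   and inside the coastal polygon to call a track coastal.
#' @param assign_threshold Posterior probability above which an untracked
#'   individual is assigned (strict inequality).
#' @param alpha Significance level for the group-separation tests.
#' @param use_ssm Fit the state-space model per track? When `FALSE`, daily
#'   paths contain only observed fixes.
#' @param ssm An [ssm_config()].
#' @param n_prior_tracked Sample size for the none-coastal binomial bound
#'   (the nine turtles tracked by earlier studies in the region).
#' @return A list of class `pipeline_params`.
#' @export
pipeline_params <- function(vmax = 240, v_res = 5, min_residence_days = 15,
                            isobath_m = -50, shallow_frac = 0.5,
                            assign_threshold = 0.80, alpha = 0.05,
                            use_ssm = TRUE, ssm = ssm_config(),
                            n_prior_tracked = 9) {
  stopifnot(vmax > 0, v_res > 0, min_residence_days > 0,
            assign_threshold > 0.5, assign_threshold < 1,
            alpha > 0, alpha < 1)
  structure(list(vmax = vmax, v_res = v_res,
                 min_residence_days = min_residence_days,
                 isobath_m = isobath_m, shallow_frac = shallow_frac,
                 assign_threshold = assign_threshold, alpha = alpha,
                 use_ssm = use_ssm, ssm = ssm,
                 n_prior_tracked = n_prior_tracked),
            class = "pipeline_params")
}

observed_only_path <- function(daily_track) {
  data.frame(date = as.Date(daily_track$timestamp, tz = "UTC"),
             lon = daily_track$lon, lat = daily_track$lat,
             source = "observed",
             lon_lo = NA_real_, lon_hi = NA_real_,
             lat_lo = NA_real_, lat_hi = NA_real_)
}

#' Run the full dual-tracer analysis
#'
#' End-to-end pipeline: Argos filtering (maximum speed, then best location
#' class per day), state-space interpolation of daily positions,
#' residence-based strategy labelling of the tracked cohort, isotope
#' aggregation and replicate QC, MANOVA / KS / Levene group checks,
#' telemetry-trained linear discriminant assignment of the untracked cohort
#' with the strict > threshold rule, jackknife cross-validation, assignment
#' proportions, and the binomial none-coastal bound. Identical inputs, params
#' and seed give an identical report.
#'
#' Behavioural metrics (speeds, residence) are computed on the state-space
#' posterior-mean path, which smooths location-class noise; the reported
#' daily positions prefer raw fixes on observed days.
#'
#' @param bundle List with `tracks`, `isotopes`, `regions`, `bathymetry`
#'   (a [simulate_study()] result, or [read_study_bundle()] output).
#' @param params A [pipeline_params()].
#' @param seed Integer master seed; per-animal child seeds are drawn from it
#'   so individual model fits are reproducible in isolation.
#' @param verbose Emit one progress line per stage?
#' @return An `analysis_report` list; see the vignette for the section
#'   layout.
#' @export
run_analysis <- function(bundle, params = pipeline_params(), seed = 1,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  for (nm in c("tracks", "isotopes", "regions", "bathymetry")) {
    if (is.null(bundle[[nm]])) stop("bundle is missing '", nm, "'", call. = FALSE)
  }
  set.seed(seed)
  animal_ids <- unique(bundle$tracks$animal_id)
  child_seed <- stats::setNames(
    sample.int(.Machine$integer.max - 1, length(animal_ids)), animal_ids)

  # --- movement pipeline per tracked animal ---------------------------------
  n_raw <- nrow(bundle$tracks)
  filtered <- speed_filter(bundle$tracks, vmax = params$vmax)
  daily <- best_daily_fix(filtered)
  say("filter: %d fixes in, %d after speed filter, %d after daily selection",
      n_raw, nrow(filtered), nrow(daily))

  telemetry <- vector("list", length(animal_ids))
  daily_paths <- vector("list", length(animal_ids))
  for (i in seq_along(animal_ids)) {
    id <- animal_ids[i]
    tr <- daily[daily$animal_id == id, , drop = FALSE]
    if (params$use_ssm && nrow(tr) >= 5) {
      set.seed(child_seed[[id]])
      post <- fit_ssm(tr, params$ssm)
      merged <- merge_daily(tr, post)
      behaviour <- ssm_point_path(post)
      frac_mod <- attr(merged, "fraction_modelled")
    } else {
      merged <- observed_only_path(tr)
      behaviour <- merged[, c("date", "lon", "lat")]
      frac_mod <- 0
    }
    lab <- classify_strategy(behaviour, bundle$regions, bundle$bathymetry,
                             v_res = params$v_res,
                             min_days = params$min_residence_days,
                             isobath_m = params$isobath_m,
                             shallow_frac = params$shallow_frac)
    telemetry[[i]] <- data.frame(animal_id = id, strategy = lab$strategy,
                                 region = lab$region,
                                 fraction_modelled = frac_mod,
                                 n_fixes = nrow(tr))
    merged$animal_id <- id
    daily_paths[[i]] <- merged
  }
  telemetry <- do.call(rbind, telemetry)
  daily_paths <- do.call(rbind, daily_paths)
  say("telemetry: %d coastal, %d oceanic; mean %.1f%% of days modelled",
      sum(telemetry$strategy == "coastal"),
      sum(telemetry$strategy == "oceanic"),
      100 * mean(telemetry$fraction_modelled))

  # --- isotopes -------------------------------------------------------------
  qc <- if (any(table(bundle$isotopes$individual_id) >= 2)) {
    qc_replicates(bundle$isotopes,
                  thresholds = c(d13C = 0.37, d15N = 0.55))
  }
  individuals <- aggregate_individuals(bundle$isotopes)
  say("isotopes: %d samples -> %d individuals", nrow(bundle$isotopes),
      nrow(individuals))

  tracked <- individuals[individuals$individual_id %in% telemetry$animal_id, ]
  untracked <- individuals[!individuals$individual_id %in% telemetry$animal_id, ]
  tracked$strategy <- telemetry$strategy[match(tracked$individual_id,
                                               telemetry$animal_id)]
  if (length(unique(tracked$strategy)) < 2) {
    stop("telemetry labels contain fewer than two strategy classes; ",
         "cannot train the discriminant", call. = FALSE)
  }

  # --- group separation and discriminant ------------------------------------
  Xtr <- as.matrix(tracked[, c("d13C", "d15N")])
  manova_res <- pillai_manova(Xtr, tracked$strategy)
  checks <- list(
    ks = list(d13C = ks_normality(tracked$d13C),
              d15N = ks_normality(tracked$d15N)),
    levene = list(d13C = levene_test(tracked$d13C, tracked$strategy),
                  d15N = levene_test(tracked$d15N, tracked$strategy))
  )
  model <- lda_train(Xtr, tracked$strategy)
  jack <- jackknife_cv(Xtr, tracked$strategy)
  say("training: Pillai p = %.3g, jackknife %d/%d correct",
      manova_res$p, jack$n_correct, jack$n)

  # --- assignment of the untracked cohort -----------------------------------
  assignments <- data.frame(
    individual_id = tracked$individual_id, species = tracked$species,
    p_coastal = NA_real_, p_oceanic = NA_real_,
    label = tracked$strategy, source = "satellite"
  )
  proportions <- NULL
  p_assigned_coastal <- NA_real_
  none_coastal <- NULL
  if (nrow(untracked) > 0) {
    post <- lda_posterior(model, as.matrix(untracked[, c("d13C", "d15N")]))
    labels <- assign_label(post, threshold = params$assign_threshold)
    assignments <- rbind(assignments, data.frame(
      individual_id = untracked$individual_id, species = untracked$species,
      p_coastal = post[, "coastal"], p_oceanic = post[, "oceanic"],
      label = labels, source = "isotope"
    ))
    proportions <- proportion_report(labels, n_tracked = nrow(tracked))
    if (proportions$n_assigned > 0) {
      p_assigned_coastal <-
        unname(proportions$counts["coastal"]) / proportions$n_assigned
      none_coastal <- list(
        p_coastal = p_assigned_coastal,
        n = params$n_prior_tracked,
        probability = prob_none_coastal(p_assigned_coastal,
                                        params$n_prior_tracked)
      )
    }
    say("assignment: %d coastal, %d oceanic, %d unassigned of %d",
        proportions$counts["coastal"], proportions$counts["oceanic"],
        proportions$counts["unassigned"], proportions$n_untracked)
  }
  rownames(assignments) <- NULL

  structure(list(
    telemetry = telemetry,
    daily_paths = daily_paths,
    fraction_modelled = mean(telemetry$fraction_modelled),
    qc = qc,
    individuals = individuals,
    manova = manova_res,
    checks = checks,
    model = model,
    jackknife = jack,
    assignments = assignments,
    proportions = proportions,
    none_coastal = none_coastal,
    counts = list(fixes_raw = n_raw, fixes_speed_filtered = nrow(filtered),
                  fixes_daily = nrow(daily)),
    params = params, seed = seed
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Dual-tracer foraging analysis\n")
  cat(sprintf("  tracked: %d animals (%d coastal, %d oceanic by telemetry)\n",
              nrow(x$telemetry), sum(x$telemetry$strategy == "coastal"),
              sum(x$telemetry$strategy == "oceanic")))
  cat(sprintf("  modelled daily positions: %.1f%%\n", 100 * x$fraction_modelled))
  print(x$manova)
  cat(sprintf("  jackknife: %d/%d correct (%d%%)\n", x$jackknife$n_correct,
              x$jackknife$n, round_half_up(100 * x$jackknife$accuracy)))
  if (!is.null(x$proportions)) print(x$proportions)
  if (!is.null(x$none_coastal)) {
    cat(sprintf("  P(none of %d prior-tracked coastal | p = %.3f) = %.2e\n",
                x$none_coastal$n, x$none_coastal$p_coastal,
                x$none_coastal$probability))
  }
  invisible(x)
}

#' Serialise an analysis report to JSON
#'
#' Writes the report's scalar results and per-individual assignment table;
#' identical analyses produce byte-identical files.
#'
#' @param report An `analysis_report` from [run_analysis()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  obj <- list(
    seed = report$seed,
    counts = report$counts,
    telemetry = report$telemetry,
    fraction_modelled = report$fraction_modelled,
    qc = if (!is.null(report$qc)) list(sigma = as.list(report$qc$sigma),
                                       n_groups = report$qc$n_groups),
    manova = unclass(report$manova),
    jackknife = report$jackknife[c("accuracy", "n_correct", "n")],
    assignments = report$assignments,
    proportions = if (!is.null(report$proportions)) {
      list(counts = as.list(report$proportions$counts),
           percentages = as.list(report$proportions$percentages),
           n_untracked = report$proportions$n_untracked)
    },
    none_coastal = report$none_coastal
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, na = "null")
  invisible(path)
}
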