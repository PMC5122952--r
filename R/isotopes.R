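#' Delta notation from isotope ratios
#'
#' `delta = (R_sample / R_standard - 1) * 1000`, in parts per thousand
#' relative to the standard (VPDB for carbon, atmospheric N2 for nitrogen).
#'
#' @param r_sample Heavy-to-light isotope ratio of the sample (>= 0).
#' @param r_standard Ratio of the reference standard (> 0).
#' @return Delta value(s), per mil.
#' @export
delta_from_ratios <- function(r_sample, r_standard) {
  if (any(r_standard <= 0)) stop("r_standard must be positive", call. = FALSE)
  if (any(r_sample < 0)) stop("r_sample must be non-negative", call. = FALSE)
  (r_sample / r_standard - 1) * 1000
}

#' Lipid correction for delta13C
#'
#' Optional linear post-hoc correction for lipid content:
#' `d13C' = d13C + a + b * cn_ratio`, applied only to samples whose C:N mass
#' ratio exceeds `cn_trigger`. Lipids are depleted in 13C, so samples with
#' high C:N would otherwise read artificially low. Coefficients are
#' tissue-specific and must be supplied; the correction is disabled by
#' default.
#'
#' @param d13C Measured delta13C values, per mil.
#' @param cn_ratio C:N mass ratios (may contain `NA`).
#' @param a,b Linear correction coefficients.
#' @param cn_trigger C:N value above which the correction applies. Default 3.5.
#' @param enabled Apply the correction? Default `FALSE` (identity).
#' @param missing_cn Policy when `enabled` and a C:N value is missing:
#'   `"skip"` leaves that sample uncorrected, `"strict"` errors.
#' @return Corrected delta13C values.
#' @export
lipid_correct <- function(d13C, cn_ratio = NULL, a = 0, b = 0,
                          cn_trigger = 3.5, enabled = FALSE,
                          missing_cn = c("skip", "strict")) {
  if (!enabled) return(d13C)
  missing_cn <- match.arg(missing_cn)
  if (is.null(cn_ratio)) cn_ratio <- rep(NA_real_, length(d13C))
  if (missing_cn == "strict" && any(is.na(cn_ratio))) {
    stop("lipid correction enabled but C:N ratio missing", call. = FALSE)
  }
  apply_to <- !is.na(cn_ratio) & cn_ratio > cn_trigger
  d13C[apply_to] <- d13C[apply_to] + a + b * cn_ratio[apply_to]
  d13C
}

#' Read isotope sample tables
#'
#' CSV schema: `sample_id,individual_id,species,d13C,d15N,cn_ratio,
#' replicate_of` (the last two may be empty). Values outside a generous
#' plausibility window (-60 < d13C < 10, -10 < d15N < 30 per mil) are
#' rejected with their row number unless `check_range = FALSE`.
#'
#' @param path CSV file path.
#' @param check_range Enforce the plausibility gate? Default `TRUE`.
#' @return Data frame of measurements.
#' @export
read_isotopes <- function(path, check_range = TRUE) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("sample_id", "individual_id", "species", "d13C", "d15N")
  if (!all(need %in% names(df))) {
    stop("isotope file must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  if (!"cn_ratio" %in% names(df)) df$cn_ratio <- NA
  if (!"replicate_of" %in% names(df)) df$replicate_of <- NA
  df$d13C <- suppressWarnings(as.numeric(df$d13C))
  df$d15N <- suppressWarnings(as.numeric(df$d15N))
  df$cn_ratio <- suppressWarnings(as.numeric(df$cn_ratio))
  df$replicate_of[!nzchar(trimws(as.character(df$replicate_of)))] <- NA
  bad <- which(!is.finite(df$d13C) | !is.finite(df$d15N))
  if (length(bad)) stop("row ", bad[1], ": non-numeric delta value", call. = FALSE)
  if (check_range) {
    bad <- which(df$d13C <= -60 | df$d13C >= 10 | df$d15N <= -10 | df$d15N >= 30)
    if (length(bad)) {
      stop("row ", bad[1], ": delta value outside plausible range ",
           "(use check_range = FALSE to override)", call. = FALSE)
    }
  }
  df
}

#' @rdname read_isotopes
#' @param measurements Measurement data frame.
#' @export
write_isotopes <- function(measurements, path) {
  cols <- c("sample_id", "individual_id", "species", "d13C", "d15N",
            "cn_ratio", "replicate_of")
  df <- measurements[, intersect(cols, names(measurements))]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Aggregate replicate samples to one record per individual
#'
#' Individuals sampled more than once get the arithmetic mean of their
#' delta13C and delta15N values. Output order follows first appearance.
#'
#' @param measurements Data frame with `individual_id`, `species`, `d13C`,
#'   `d15N` (one row per sample).
#' @return Data frame with one row per individual: `individual_id`,
#'   `species`, `d13C`, `d15N`, `n_samples`.
#' @export
aggregate_individuals <- function(measurements) {
  if (nrow(measurements) == 0) {
    return(data.frame(individual_id = character(), species = character(),
                      d13C = numeric(), d15N = numeric(),
                      n_samples = integer()))
  }
  ids <- unique(measurements$individual_id)
  rows <- lapply(ids, function(id) {
    m <- measurements[measurements$individual_id == id, , drop = FALSE]
    sp <- unique(m$species)
    if (length(sp) != 1) {
      stop("individual '", id, "' has conflicting species: ",
           paste(sp, collapse = ", "), call. = FALSE)
    }
    data.frame(individual_id = id, species = sp,
               d13C = mean(m$d13C), d15N = mean(m$d15N),
               n_samples = nrow(m))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Replicate quality control
#'
#' Pooled within-group standard deviation of duplicate (or higher-order
#' replicate) measurements per element:
#' `sqrt(sum of within-group squared deviations / sum(n_i - 1))`, compared
#' against an acceptance threshold per element. For a single duplicate pair
#' this reduces to `|difference| / sqrt(2)`.
#'
#' @param measurements Data frame with `individual_id`, `d13C`, `d15N`; only
#'   individuals with two or more samples contribute.
#' @param thresholds Named vector of acceptance thresholds, per mil. The
#'   defaults (0.2 for d13C, 0.35 for d15N) are the tolerances used for
#'   reference-standard replicates.
#' @return List with `sigma` (named pooled-sd vector), `pass` (named logical),
#'   `n_groups` and `n_samples`.
#' @export
qc_replicates <- function(measurements,
                          thresholds = c(d13C = 0.2, d15N = 0.35)) {
  tab <- table(measurements$individual_id)
  dup_ids <- names(tab)[tab >= 2]
  if (length(dup_ids) == 0) stop("no replicated individuals", call. = FALSE)
  m <- measurements[measurements$individual_id %in% dup_ids, , drop = FALSE]
  pooled <- function(values, group) {
    ss <- tapply(values, group, function(v) sum((v - mean(v))^2))
    df <- tapply(values, group, function(v) length(v) - 1)
    sqrt(sum(ss) / sum(df))
  }
  sigma <- c(d13C = pooled(m$d13C, m$individual_id),
             d15N = pooled(m$d15N, m$individual_id))
  list(sigma = sigma,
       pass = sigma <= thresholds[names(sigma)],
       n_groups = length(dup_ids),
       n_samples = nrow(m))
}
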