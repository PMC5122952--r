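#' Default Argos location-class error scales
#'
#' One standard-deviation position error per location class, in degrees
#' (roughly 0.25, 0.5, 1.5, 5, 8 and 12 km for classes 3, 2, 1, 0, A, B —
#' the magnitudes reported for Argos by validation studies on marine
#' megafauna). The same table drives the synthetic-track noise generator and
#' the state-space observation model, which uses the scales relative to
#' class 3 as fixed multipliers on its estimated base scale.
#'
#' @return Named numeric vector over classes `3,2,1,0,A,B`.
#' @export
argos_lc_scales <- function() {
  c("3" = 0.0022, "2" = 0.0045, "1" = 0.0135,
    "0" = 0.045, "A" = 0.072, "B" = 0.108)
}

#' Default Argos location-class frequency table
#'
#' Relative frequency with which each class is observed; used by the
#' synthetic-track generator.
#'
#' @return Named probability vector over classes `3,2,1,0,A,B`.
#' @export
argos_lc_freq <- function() {
  c("3" = 0.15, "2" = 0.20, "1" = 0.25, "0" = 0.15, "A" = 0.15, "B" = 0.10)
}
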