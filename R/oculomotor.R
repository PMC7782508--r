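#' Saccade landing-position noise model
#'
#' Eccentricity-dependent scatter and undershoot of saccade landing positions.
#' The scatter SD grows linearly with the saccade-target eccentricity,
#' \eqn{\sigma_s = 0.0453 x + 0.364} (deg), and long saccades undershoot with
#' bias \eqn{-\max(0, x - 10) \times 0.1195} (deg) along the saccade axis.
#' Defaults are the coefficients estimated from visually guided saccades.
#'
#' @param sd_slope,sd_intercept linear coefficients of the scatter SD.
#' @param bias_slope undershoot growth rate beyond the onset eccentricity.
#' @param bias_onset eccentricity (deg) beyond which undershoot appears.
#' @param enabled logical; `FALSE` makes saccades land exactly on target.
#' @return object of class `landing_model`.
#' @export
landing_model <- function(sd_slope = 0.0453, sd_intercept = 0.364,
                          bias_slope = 0.1195, bias_onset = 10,
                          enabled = TRUE) {
  if (sd_intercept <= 0) stop("sd_intercept must be positive")
  structure(list(sd_slope = sd_slope, sd_intercept = sd_intercept,
                 bias_slope = bias_slope, bias_onset = bias_onset,
                 enabled = enabled),
            class = "landing_model")
}

#' Landing-scatter SD at a saccade amplitude
#'
#' @param ecc saccade-target eccentricity from the current fixation (deg,
#'   non-negative, vectorized).
#' @param lm a [landing_model()].
#' @return SD in degrees.
#' @export
landing_sd <- function(ecc, lm = landing_model()) {
  if (any(ecc < 0)) stop("eccentricity must be non-negative")
  lm$sd_slope * ecc + lm$sd_intercept
}

#' Saccadic undershoot bias at a saccade amplitude
#'
#' @param ecc saccade-target eccentricity (deg, non-negative, vectorized).
#' @param lm a [landing_model()].
#' @return signed along-axis bias in degrees (<= 0; undershoot).
#' @export
landing_bias <- function(ecc, lm = landing_model()) {
  if (any(ecc < 0)) stop("eccentricity must be non-negative")
  -pmax(0, ecc - lm$bias_onset) * lm$bias_slope
}

#' Sample a saccade landing position
#'
#' The landing distribution is an isotropic 2-D Gaussian centered on the
#' saccade target displaced along the saccade axis toward the current fixation
#' by the undershoot bias, with per-axis SD given by [landing_sd()] at the
#' planned amplitude.  Samples outside the field are redrawn (up to
#' `max_attempts`), then clamped to the rim.
#'
#' @param current length-2 current fixation (deg).
#' @param target length-2 saccade target (deg).
#' @param lm a [landing_model()].
#' @param field_radius field radius (deg).
#' @param max_attempts resampling budget for out-of-field landings.
#' @return length-2 landing position (deg).
#' @export
sample_landing <- function(current, target, lm = landing_model(),
                           field_radius = 7.5, max_attempts = 100) {
  if (!lm$enabled) return(target)
  dx <- target[1] - current[1]
  dy <- target[2] - current[2]
  amp <- sqrt(dx^2 + dy^2)
  s <- landing_sd(amp, lm)
  b <- landing_bias(amp, lm)
  # b <= 0: displace from the target back toward the current fixation
  mu <- if (amp > 0) target + b * c(dx, dy) / amp else target
  for (i in seq_len(max_attempts)) {
    land <- mu + rnorm(2, 0, s)
    if (sum(land^2) <= field_radius^2) return(land)
  }
  land / sqrt(sum(land^2)) * field_radius
}
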