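#' Seawater environment profile
#'
#' Bundles the water properties that control sound speed and absorption.
#' The two field sites analysed by this package correspond to
#' `environment_profile(9.2, 33.9)` (British Columbia) and
#' `environment_profile(15, 20)` (inner Danish waters); the detection-range
#' model defaults to 14 degC and 33 ppt.
#'
#' @param temperature Water temperature, degC. Must lie in [-2, 40].
#' @param salinity Salinity, parts per thousand. Must lie in [0, 45].
#' @param depth Nominal depth, m (near-surface recordings; affects sound
#'   speed only marginally and absorption pressure terms not at all here).
#' @param sound_speed Optional fixed sound speed, m/s; derived from
#'   temperature/salinity/depth when `NULL`.
#' @param ph pH, used by the Ainslie-McColm absorption formulation.
#' @return An object of class `environment_profile`.
#' @export
environment_profile <- function(temperature, salinity, depth = 5,
                                sound_speed = NULL, ph = 8) {
  stopifnot(is.numeric(temperature), is.numeric(salinity))
  if (temperature < -2 || temperature > 40) {
    stop("temperature out of supported range [-2, 40] degC", call. = FALSE)
  }
  if (salinity < 0 || salinity > 45) {
    stop("salinity out of supported range [0, 45] ppt", call. = FALSE)
  }
  env <- structure(
    list(temperature = temperature, salinity = salinity, depth = depth,
         sound_speed = sound_speed, ph = ph),
    class = "environment_profile"
  )
  cs <- sound_speed_mps(env)
  if (is.null(sound_speed) && (cs < 1400 || cs > 1600)) {
    stop("derived sound speed outside [1400, 1600] m/s", call. = FALSE)
  }
  env
}

#' @export
print.environment_profile <- function(x, ...) {
  cat(sprintf(
    "<environment_profile> T = %.1f degC, S = %.1f ppt, depth = %.1f m, c = %.1f m/s\n",
    x$temperature, x$salinity, x$depth, sound_speed_mps(x)))
  invisible(x)
}

#' Seawater sound speed
#'
#' Sound speed from the Coppens (1981) formula, valid for 0-35 degC,
#' 0-45 ppt and depths to 4 km. If the profile carries a fixed
#' `sound_speed` it is returned unchanged.
#'
#' @param env An [environment_profile].
#' @return Sound speed in m/s, with the formula name attached as the
#'   `formulation` attribute.
#' @examples
#' sound_speed_mps(environment_profile(15, 20))
#' @export
sound_speed_mps <- function(env) {
  stopifnot(inherits(env, "environment_profile"))
  if (!is.null(env$sound_speed)) {
    return(structure(env$sound_speed, formulation = "fixed"))
  }
  t <- env$temperature / 10
  s <- env$salinity
  d <- env$depth / 1000  # km
  c0 <- 1449.05 + 45.7 * t - 5.21 * t^2 + 0.23 * t^3 +
    (1.333 - 0.126 * t + 0.009 * t^2) * (s - 35)
  cs <- c0 + (16.23 + 0.253 * t) * d + (0.213 - 0.1 * t) * d^2 +
    (0.016 + 0.0002 * (s - 35)) * (s - 35) * t * d
  structure(cs, formulation = "coppens1981")
}

# Fisher & Simmons (1977)-style absorption, dB/m, f in Hz, near-surface
# (pressure correction terms ~1). The published equations are for S = 35 ppt;
# the boric-acid and magnesium-sulfate relaxation terms scale with the ionic
# content and are multiplied by S/35 for other salinities. Valid inputs are
# not range-checked here; the exported wrapper enforces the supported band.
alpha_fisher_simmons <- function(f_hz, temperature, salinity) {
  t <- temperature
  theta <- t + 273.1
  f1 <- 1315 * theta * exp(-1700 / theta)
  f2 <- 1.55e7 * theta * exp(-3052 / theta)
  a_bor <- 8.95e-8 * (1 + 2.3e-2 * t - 5.1e-4 * t^2)
  a_mgs <- 4.88e-7 * (1 + 1.3e-2 * t)
  a_vis <- 4.876e-13 * (1 - 4.0e-2 * t + 5.9e-4 * t^2)
  srat <- salinity / 35
  srat * a_bor * f1 * f_hz^2 / (f1^2 + f_hz^2) +
    srat * a_mgs * f2 * f_hz^2 / (f2^2 + f_hz^2) +
    a_vis * f_hz^2
}

# Ainslie & McColm (1998) simplified absorption, dB/m, f in kHz.
alpha_ainslie_mccolm <- function(f_khz, temperature, salinity, depth_m = 5,
                                 ph = 8) {
  t <- temperature
  s <- salinity
  z <- depth_m / 1000  # km
  f1 <- 0.78 * sqrt(s / 35) * exp(t / 26)
  f2 <- 42 * exp(t / 17)
  a_bor <- 0.106 * (f1 * f_khz^2 / (f1^2 + f_khz^2)) * exp((ph - 8) / 0.56)
  a_mgs <- 0.52 * (1 + t / 43) * (s / 35) *
    (f2 * f_khz^2 / (f2^2 + f_khz^2)) * exp(-z / 6)
  a_vis <- 0.00049 * f_khz^2 * exp(-(t / 27 + z / 17))
  (a_bor + a_mgs + a_vis) / 1000
}

#' Frequency-dependent seawater absorption coefficient
#'
#' Absorption in dB/m with boric-acid, magnesium-sulfate and viscous
#' relaxation terms. The default is the Fisher & Simmons (1977) formulation
#' evaluated near the surface at pH 8, with the two relaxation terms scaled
#' by S/35 for salinities away from 35 ppt; Ainslie & McColm (1998) is
#' available as a sensitivity alternative.
#'
#' For back-calculating broadband source levels the coefficient is evaluated
#' at a single frequency, conventionally the mean centroid frequency of the
#' clicks under study.
#'
#' @param f_khz Frequency (or vector of frequencies), kHz; supported band
#'   10-250 kHz.
#' @param env An [environment_profile].
#' @param formulation `"fisher_simmons"` (default) or `"ainslie_mccolm"`.
#' @return Absorption coefficient(s), dB/m.
#' @examples
#' bc <- environment_profile(9.2, 33.9)
#' absorption_coefficient(137, bc)
#' @export
absorption_coefficient <- function(f_khz, env,
                                   formulation = c("fisher_simmons",
                                                   "ainslie_mccolm")) {
  stopifnot(inherits(env, "environment_profile"))
  formulation <- match.arg(formulation)
  if (any(f_khz < 10 | f_khz > 250)) {
    stop("frequency outside supported band [10, 250] kHz", call. = FALSE)
  }
  alpha_db_per_m(f_khz, env, formulation)
}

# Internal evaluator without the band check, used for per-bin filtering of
# full spectra (bins run from 0 Hz to Nyquist; the formulae behave sensibly
# there, tending to 0 as f -> 0).
alpha_db_per_m <- function(f_khz, env, formulation = "fisher_simmons") {
  switch(formulation,
    fisher_simmons = alpha_fisher_simmons(f_khz * 1e3, env$temperature,
                                          env$salinity),
    ainslie_mccolm = alpha_ainslie_mccolm(f_khz, env$temperature,
                                          env$salinity, env$depth, env$ph),
    stop("unknown absorption formulation: ", formulation, call. = FALSE)
  )
}

#' Transmission loss
#'
#' Spherical spreading plus linear absorption:
#' `TL = 20*log10(r) + alpha * r`.
#'
#' @param range_m Range in meters (> 0).
#' @param alpha_db_m Absorption coefficient, dB/m.
#' @return Transmission loss, dB.
#' @export
transmission_loss <- function(range_m, alpha_db_m) {
  stopifnot(all(range_m > 0), all(alpha_db_m >= 0))
  20 * log10(range_m) + alpha_db_m * range_m
}
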