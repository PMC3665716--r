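#' Ambient noise spectral model
#'
#' Background spectral noise level `N0(f)` (dB re 1 uPa^2/Hz) for the
#' detection-range model. The default is a documented parametric stand-in
#' for classical deep-water ambient noise curves: a wind/sea-state term
#' falling 17 dB per decade from `wind_level_1khz` at 1 kHz, plus a thermal
#' term rising 20 dB per decade (`-15 + 20*log10(f_kHz)`), power-summed.
#' Their intersection produces the low-noise window around 100-150 kHz that
#' NBHF clicks are thought to exploit; with the sea-state-3 default the
#' spectral minimum falls near 120 kHz. A measured curve can be supplied as
#' a two-column table (kHz, dB re 1 uPa^2/Hz) and is interpolated linearly
#' in dB over log frequency.
#'
#' @param sea_state Sea state (scales the wind term by 2.5 dB per state
#'   around sea state 3).
#' @param wind_level_1khz Wind-noise spectral level at 1 kHz for sea state
#'   3, dB re 1 uPa^2/Hz.
#' @param table Optional data frame with columns `freq_khz` and
#'   `spectral_db` overriding the parametric model.
#' @return A `noise_model` object.
#' @export
noise_model <- function(sea_state = 3, wind_level_1khz = 62, table = NULL) {
  if (!is.null(table)) {
    stopifnot(all(c("freq_khz", "spectral_db") %in% names(table)),
              nrow(table) >= 2)
    structure(list(type = "table",
                   table = tibble::as_tibble(table),
                   support_khz = range(table$freq_khz)),
              class = "noise_model")
  } else {
    structure(list(type = "parametric", sea_state = sea_state,
                   wind_level_1khz = wind_level_1khz +
                     2.5 * (sea_state - 3),
                   support_khz = c(1, 250)),
              class = "noise_model")
  }
}

#' @export
print.noise_model <- function(x, ...) {
  if (x$type == "parametric") {
    cat(sprintf(
      "<noise_model> parametric deep-water stand-in, sea state %g (wind %g dB at 1 kHz + thermal)\n",
      x$sea_state, x$wind_level_1khz))
  } else {
    cat(sprintf("<noise_model> tabulated, %d points on [%g, %g] kHz\n",
                nrow(x$table), x$support_khz[1], x$support_khz[2]))
  }
  invisible(x)
}

#' Spectral noise level at a frequency
#'
#' @param f_khz Frequency (vector), kHz; must lie in the model support.
#' @param nm A [noise_model].
#' @return Spectral level(s), dB re 1 uPa^2/Hz.
#' @export
noise_spectral_level <- function(f_khz, nm = noise_model()) {
  stopifnot(inherits(nm, "noise_model"))
  if (any(f_khz < nm$support_khz[1] | f_khz > nm$support_khz[2])) {
    stop("frequency outside noise-model support [",
         nm$support_khz[1], ", ", nm$support_khz[2], "] kHz", call. = FALSE)
  }
  if (nm$type == "table") {
    stats::approx(log10(nm$table$freq_khz), nm$table$spectral_db,
                  xout = log10(f_khz))$y
  } else {
    wind <- nm$wind_level_1khz - 17 * log10(f_khz)
    thermal <- -15 + 20 * log10(f_khz)
    10 * log10(10^(wind / 10) + 10^(thermal / 10))
  }
}

#' Masking noise level for a click
#'
#' `NL = N0(Fc) + 10*log10(BW_RMS)`: spectral noise at the centroid
#' frequency plus the bandwidth term of an energy detector whose receiving
#' band matches the click's rms bandwidth. Bandwidth enters in Hz; since
#' the detection-range model only ever compares scenarios, only bandwidth
#' ratios matter.
#'
#' @param fc_khz Centroid frequency, kHz.
#' @param bw_rms_khz Rms bandwidth, kHz.
#' @param nm A [noise_model].
#' @return Noise level, dB.
#' @export
noise_level <- function(fc_khz, bw_rms_khz, nm = noise_model()) {
  stopifnot(bw_rms_khz > 0)
  noise_spectral_level(fc_khz, nm) + 10 * log10(bw_rms_khz * 1e3)
}

#' Sonar scenario for the detection-range model
#'
#' A click design to feed into the active sonar equation
#' `ENR = SL - 2*TL + TS + DI - NL`: centroid frequency and rms bandwidth
#' vary between scenarios while source energy flux density, target
#' strength, receiving directivity index and the detection-threshold ENR
#' are held fixed (and therefore cancel when scenarios are compared).
#'
#' @param fc_khz Centroid frequency, kHz.
#' @param bw_rms_khz Rms bandwidth, kHz.
#' @param environment An [environment_profile]; defaults to 14 degC, 33 ppt
#'   (the detection-range model conditions).
#' @param label Scenario label.
#' @param sl_efd,ts,di_receive,dt_enr The shared fixed terms, dB; must be
#'   identical across compared scenarios.
#' @return A `sonar_scenario` object.
#' @export
sonar_scenario <- function(fc_khz, bw_rms_khz,
                           environment = environment_profile(14, 33),
                           label = sprintf("%g kHz / %g kHz", fc_khz,
                                           bw_rms_khz),
                           sl_efd = 0, ts = 0, di_receive = 0, dt_enr = 0) {
  stopifnot(fc_khz > 0, bw_rms_khz > 0,
            inherits(environment, "environment_profile"))
  structure(
    list(fc_khz = fc_khz, bw_rms_khz = bw_rms_khz,
         environment = environment, label = label,
         sl_efd = sl_efd, ts = ts, di_receive = di_receive,
         dt_enr = dt_enr),
    class = "sonar_scenario"
  )
}

#' Echo-to-noise-ratio difference curve versus a reference click
#'
#' Computes `deltaENR(r)`, the echo-to-noise ratio of a scenario minus that
#' of the reference scenario (conventionally the 130 kHz / 15 kHz NBHF
#' design) at the same target range. With source energy flux density,
#' target strength, receiving DI and detection threshold fixed across
#' scenarios, the spreading terms cancel and
#'
#' `deltaENR(r) = -2r*(alpha(fc) - alpha(fc_ref)) - (N0(fc) - N0(fc_ref))
#'               - 10*log10(bw/bw_ref)`.
#'
#' Positive values mean the scenario out-detects the reference at that
#' range; 0 dB is the reference NBHF echo at its detection threshold.
#'
#' @param s A [sonar_scenario].
#' @param reference The reference [sonar_scenario]; its fixed fields and
#'   environment must match `s`.
#' @param ranges_m Range grid, m.
#' @param nm A [noise_model].
#' @param formulation Absorption formulation.
#' @return A `detection_curve` tibble: `range_m`, `delta_enr_db`,
#'   `scenario`; the three additive terms are stored in the `terms`
#'   attribute.
#' @export
delta_enr_curve <- function(s, reference, ranges_m = seq(1, 1000, by = 1),
                            nm = noise_model(),
                            formulation = "fisher_simmons") {
  stopifnot(inherits(s, "sonar_scenario"),
            inherits(reference, "sonar_scenario"))
  fixed <- c("sl_efd", "ts", "di_receive", "dt_enr")
  if (!isTRUE(all.equal(s[fixed], reference[fixed])) ||
      !isTRUE(all.equal(s$environment, reference$environment))) {
    stop("scenario and reference must share fixed terms and environment",
         call. = FALSE)
  }
  env <- s$environment
  d_alpha <- absorption_coefficient(s$fc_khz, env, formulation) -
    absorption_coefficient(reference$fc_khz, env, formulation)
  d_noise <- noise_spectral_level(s$fc_khz, nm) -
    noise_spectral_level(reference$fc_khz, nm)
  d_bw <- 10 * log10(s$bw_rms_khz / reference$bw_rms_khz)
  out <- tibble::tibble(
    range_m = ranges_m,
    delta_enr_db = -2 * ranges_m * d_alpha - d_noise - d_bw,
    scenario = s$label
  )
  structure(out,
            class = c("detection_curve", class(out)),
            terms = list(absorption_db_per_m = d_alpha,
                         noise_window_db = d_noise,
                         bandwidth_db = d_bw),
            reference = reference$label)
}

#' First range where a detection curve crosses the reference
#'
#' Finds, per scenario, the first range at which `deltaENR` crosses 0
#' (linear interpolation between grid points): the range beyond which that
#' click design starts to out-detect the reference. Curves that never cross
#' within the grid — including the reference curve itself, identically
#' zero — report `NA`. If a curve crosses more than once the first crossing
#' is returned with a warning.
#'
#' @param curves A `detection_curve` tibble (or several row-bound
#'   together), columns `range_m`, `delta_enr_db`, `scenario`.
#' @return A tibble with `scenario` and `crossover_range_m`.
#' @export
crossover_ranges <- function(curves) {
  stopifnot(all(c("range_m", "delta_enr_db", "scenario") %in%
                  names(curves)))
  curves |>
    dplyr::group_by(.data$scenario) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$range_m)
      y <- d$delta_enr_db
      if (all(abs(y) < 1e-12)) {
        return(tibble::tibble(crossover_range_m = NA_real_))
      }
      sgn <- sign(y)
      idx <- which(sgn[-1] != sgn[-length(sgn)] & sgn[-1] != 0)
      if (!length(idx)) {
        z <- which(y == 0)
        return(tibble::tibble(
          crossover_range_m = if (length(z)) d$range_m[z[1]] else NA_real_))
      }
      if (length(idx) > 1) {
        warning("multiple zero crossings for scenario '", key$scenario,
                "'; returning the first")
      }
      i <- idx[1]
      r0 <- d$range_m[i] + (d$range_m[i + 1] - d$range_m[i]) *
        (0 - y[i]) / (y[i + 1] - y[i])
      tibble::tibble(crossover_range_m = r0)
    }) |>
    dplyr::ungroup()
}

#' Peak-pressure level for equal energy flux density
#'
#' Clicks of identical envelope shape have equal source energy flux density
#' when `pp + 10*log10(duration)` is equal, so a shorter click must make up
#' the duration ratio in pressure:
#' `sl_pp_b = sl_pp_a + 10*log10(duration_a / duration_b)`. A 100 us NBHF
#' click at 200 dB pp therefore matches the energy flux density of a 25 us
#' dolphin-style click at 206 dB pp.
#'
#' @param duration_a_us Duration of the reference click, us.
#' @param sl_pp_a_db Peak-peak source level of the reference click, dB re
#'   1 uPa pp.
#' @param duration_b_us Duration of the other click, us.
#' @return Peak-peak source level of the other click, dB re 1 uPa pp.
#' @examples
#' efd_pp_equivalence(100, 200, 25) # 206.02
#' @export
efd_pp_equivalence <- function(duration_a_us, sl_pp_a_db, duration_b_us) {
  if (duration_a_us <= 0 || duration_b_us <= 0) {
    stop("durations must be positive", call. = FALSE)
  }
  sl_pp_a_db + 10 * log10(duration_a_us / duration_b_us)
}
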