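#' Plot Monte Carlo discrimination accuracy against set size
#'
#' Mean percent correct with standard-error bars per click-set size, with
#' the 90% guide line conventionally used to judge usable discrimination.
#'
#' @param object A `mc_discrimination` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mc_discrimination
#' @export
autoplot.mc_discrimination <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$set_size,
                                  y = .data$percent_correct)) +
    ggplot2::geom_hline(yintercept = 90, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$percent_correct - .data$sem,
      ymax = .data$percent_correct + .data$sem), width = 0.05) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(trans = "log2",
                                breaks = unique(d$set_size)) +
    ggplot2::labs(
      x = "clicks per set", y = "correctly classified sets (%)",
      title = sprintf("Species discrimination at %.0f kHz criterion",
                      attr(object, "criterion_khz"))) +
    ggplot2::theme_minimal()
}

#' Plot a composite beam pattern with its piston fit
#'
#' Beam samples (dB re the on-axis level, against degrees off-axis) with
#' the fitted circular-piston curve overlaid.
#'
#' @param object A `piston_fit`.
#' @param max_angle_deg Plot range in degrees.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot piston_fit
#' @export
autoplot.piston_fit <- function(object, max_angle_deg = 30, ...) {
  th <- seq(0, max_angle_deg, length.out = 400) * pi / 180
  curve <- tibble::tibble(
    angle_deg = th * 180 / pi,
    level_db = 20 * log10(pmax(piston_beam_mag(th, object$ka), 1e-12)) +
      object$offset_db)
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(x = .data$angle_deg,
                               y = .data$relative_level_db)) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(y = .data$level_db),
                       colour = "steelblue") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_cartesian(ylim = c(-30, 2),
                             xlim = c(0, max_angle_deg)) +
    ggplot2::labs(
      x = "degrees off-axis", y = "dB re on-axis source level",
      title = sprintf("Piston fit: aperture %.1f cm, DI %.1f dB",
                      object$aperture_cm, object$directivity_index_db)) +
    ggplot2::theme_minimal()
}

#' Plot detection-range curves
#'
#' Echo-to-noise-ratio difference versus target range for one or more
#' scenarios relative to the NBHF reference; 0 dB marks performance equal
#' to the reference.
#'
#' @param object A `detection_curve` tibble (several may be row-bound).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot detection_curve
#' @export
autoplot.detection_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$range_m,
                                       y = .data$delta_enr_db,
                                       colour = .data$scenario)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "target range (m)",
                  y = expression(Delta * "ENR (dB re NBHF reference)"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ambient-noise spectral model
#'
#' @param object A `noise_model`.
#' @param f_khz Frequency grid, kHz.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot noise_model
#' @export
autoplot.noise_model <- function(object, f_khz = 10^seq(0, log10(250),
                                                        length.out = 300),
                                 ...) {
  d <- tibble::tibble(freq_khz = f_khz,
                      spectral_db = noise_spectral_level(f_khz, object))
  ggplot2::ggplot(d, ggplot2::aes(.data$freq_khz, .data$spectral_db)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "frequency (kHz)",
                  y = expression("spectral level (dB re 1" ~ mu *
                                   "Pa"^2 * "/Hz)")) +
    ggplot2::theme_minimal()
}
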