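#' Envelope-domain click metrics
#'
#' Computes the time-domain source parameters of a click snippet from the
#' magnitude of its analytic signal (Hilbert envelope):
#' * `duration_10db_us` — span between the first and last crossings of the
#'   level 10 dB below the envelope peak (sub-sample, linearly
#'   interpolated);
#' * `rl_pp_db` — `20*log10(max - min)` of the instantaneous pressure;
#' * `rl_rms_db` — rms pressure over the -10 dB window only;
#' * `rl_efd_db` — energy flux density (integral of squared pressure) over
#'   the -10 dB window, dB re 1 uPa^2 s.
#'
#' @param w A [click_waveform] fully containing the click: the envelope peak
#'   must not sit on either edge of the snippet.
#' @return A one-row tibble with the four metrics.
#' @export
compute_envelope_metrics <- function(w) {
  stopifnot(inherits(w, "click_waveform"))
  s <- w$samples
  env <- signal_envelope(s)
  ipk <- which.max(env)
  # a small margin beats analytic-signal edge ripple on truncated clicks
  edge <- max(2L, ceiling(length(env) / 100))
  if (ipk <= edge || ipk > length(env) - edge) {
    stop("truncated click: envelope peak at snippet edge", call. = FALSE)
  }
  thr <- env[ipk] * 10^(-10 / 20)
  above <- env >= thr
  i1 <- which(above)[1]
  i2 <- rev(which(above))[1]
  # sub-sample crossing interpolation
  t1 <- if (i1 > 1) {
    (i1 - 1) - (env[i1] - thr) / (env[i1] - env[i1 - 1])
  } else 0
  t2 <- if (i2 < length(env)) {
    (i2 - 1) + (env[i2] - thr) / (env[i2] - env[i2 + 1])
  } else length(env) - 1
  dt <- 1 / w$sample_rate
  dur_us <- (t2 - t1) * dt * 1e6

  win <- max(1, floor(t1) + 1):min(length(s), ceiling(t2) + 1)
  pw <- s[win]
  ms_pw <- mean(pw^2)
  # energy integrated over the (sub-sample interpolated) -10 dB duration:
  # mean power in the window times the duration, which keeps
  # EFD = RMS level + 10log10(duration) exact at any sampling grid
  tibble::tibble(
    duration_10db_us = dur_us,
    rl_pp_db = 20 * log10(max(s) - min(s)),
    rl_rms_db = 20 * log10(sqrt(ms_pw)),
    rl_efd_db = 10 * log10(ms_pw * dur_us * 1e-6)
  )
}

#' Spectral click metrics
#'
#' Computes the frequency-domain source parameters from a rectangular-window
#' power spectrum: an `nfft`-point segment centered on the envelope peak,
#' zero-padded by `interp_factor` (realizing the conventional "interpolated
#' spectrum"). Parameters:
#' * `f_peak_khz` — frequency of the spectral maximum;
#' * `f_centroid_khz` — by default the frequency dividing the spectrum into
#'   two halves of equal energy (spectral median); set
#'   `centroid_method = "mean"` for the energy-weighted mean instead;
#' * `bw_rms_khz` — energy-weighted spectral standard deviation about the
#'   centroid, on a linear scale;
#' * `bw_3db_khz`, `bw_10db_khz` — widths of the contiguous region around
#'   the global spectral peak above -3/-10 dB re peak (interpolated
#'   crossings);
#' * `q_rms = f_centroid / bw_rms`, `q_3db = f_peak / bw_3db`.
#'
#' @param w A [click_waveform].
#' @param nfft Transform segment length in samples (default 512).
#' @param interp_factor Zero-padding factor for spectrum interpolation
#'   (default 10).
#' @param centroid_method `"median"` (equal-energy split, default) or
#'   `"mean"` (energy-weighted mean).
#' @return A one-row tibble with the seven spectral metrics.
#' @export
compute_spectral_metrics <- function(w, nfft = 512, interp_factor = 10,
                                     centroid_method = c("median", "mean")) {
  stopifnot(inherits(w, "click_waveform"), interp_factor >= 1)
  centroid_method <- match.arg(centroid_method)
  spec <- click_power_spectrum(w, nfft, interp_factor)
  f <- spec$f_khz
  P <- spec$power

  f_peak <- f[which.max(P)]
  cum <- cumsum(P)
  tot <- cum[length(cum)]
  f_centroid_median <- {
    i <- which(cum >= tot / 2)[1]
    if (i == 1) f[1] else {
      f[i - 1] + (f[i] - f[i - 1]) * (tot / 2 - cum[i - 1]) /
        (cum[i] - cum[i - 1])
    }
  }
  f_centroid_mean <- sum(f * P) / tot
  f_centroid <- if (centroid_method == "median") f_centroid_median else
    f_centroid_mean
  bw_rms <- sqrt(sum(P * (f - f_centroid)^2) / tot)

  bw_3db <- db_bandwidth(f, P, -3)
  bw_10db <- db_bandwidth(f, P, -10)

  tibble::tibble(
    f_peak_khz = f_peak, f_centroid_khz = f_centroid,
    bw_3db_khz = bw_3db, bw_10db_khz = bw_10db, bw_rms_khz = bw_rms,
    q_rms = f_centroid / bw_rms, q_3db = f_peak / bw_3db
  )
}

# One-sided interpolated power spectrum of the nfft segment centered on the
# envelope peak. Errors if the click's -10 dB extent exceeds the segment.
click_power_spectrum <- function(w, nfft = 512, interp_factor = 10) {
  s <- w$samples
  env <- signal_envelope(s)
  ipk <- which.max(env)
  thr <- env[ipk] * 10^(-10 / 20)
  ext <- range(which(env >= thr))
  if (diff(ext) + 1 > nfft) {
    stop("window too short: click -10 dB extent exceeds the ", nfft,
         "-sample segment", call. = FALSE)
  }
  half <- nfft %/% 2
  idx <- (ipk - half):(ipk + half - 1)
  seg <- numeric(nfft)
  ok <- idx >= 1 & idx <= length(s)
  seg[ok] <- s[idx[ok]]
  nz <- nfft * interp_factor
  X <- stats::fft(c(seg, numeric(nz - nfft)))
  half_bins <- 1:(nz %/% 2 + 1)
  list(f_khz = (half_bins - 1) * w$sample_rate / nz / 1e3,
       power = Mod(X[half_bins])^2)
}

# Width (kHz) of the contiguous region around the global spectral peak that
# stays above `level_db` re the peak, with linearly interpolated edge
# crossings. The contiguous-region rule is the deterministic tie-break when
# side lobes re-cross the threshold.
db_bandwidth <- function(f, P, level_db) {
  ipk <- which.max(P)
  thr <- P[ipk] * 10^(level_db / 10)
  lo <- ipk
  while (lo > 1 && P[lo - 1] >= thr) lo <- lo - 1
  hi <- ipk
  while (hi < length(P) && P[hi + 1] >= thr) hi <- hi + 1
  f_lo <- if (lo > 1) {
    f[lo] - (f[lo] - f[lo - 1]) * (P[lo] - thr) / (P[lo] - P[lo - 1])
  } else f[1]
  f_hi <- if (hi < length(P)) {
    f[hi] + (f[hi + 1] - f[hi]) * (P[hi] - thr) / (P[hi] - P[hi + 1])
  } else f[length(f)]
  f_hi - f_lo
}

#' All click source parameters
#'
#' Convenience wrapper combining [compute_envelope_metrics()] and
#' [compute_spectral_metrics()] into the standard eleven-parameter
#' description of an on-axis click.
#'
#' @inheritParams compute_spectral_metrics
#' @return A one-row tibble with the eleven source parameters.
#' @export
click_parameters <- function(w, nfft = 512, interp_factor = 10,
                             centroid_method = "median") {
  dplyr::bind_cols(
    compute_envelope_metrics(w),
    compute_spectral_metrics(w, nfft, interp_factor, centroid_method)
  )
}
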