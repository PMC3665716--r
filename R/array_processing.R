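#' Detect clicks and group them into scans
#'
#' Per-channel envelope detector with cross-channel coincidence merging.
#' Each channel's Hilbert envelope is compared against a threshold
#' `threshold_db` above its noise floor (the median envelope, a robust
#' noise statistic in click-sparse recordings); local maxima separated by at
#' least `min_sep_ms` become channel events. Events coincident across
#' channels within the maximum inter-hydrophone travel time are merged into
#' one click. Clicks separated by more than `scan_gap_ms` start a new scan;
#' the inter-click-interval series of a scan is computed on the peak
#' channel's arrival times.
#'
#' @param recording An `array_recording` (see [render_array_recording()] or
#'   [read_multichannel_wav()]).
#' @param threshold_db Detection threshold above the per-channel noise
#'   floor, dB (> 0).
#' @param scan_gap_ms Gap that terminates a scan, ms.
#' @param min_sep_ms Minimum separation between events on one channel, ms.
#' @param snippet_ms Length of the waveform snippet cut around each
#'   per-channel event, ms.
#' @return A list of `scan_segment` objects; each holds `clicks` (tibble:
#'   `click_id`, `time_s`, `peak_channel`, `n_channels`, per-channel
#'   peak-peak received level columns), `snippets` (list: click, then
#'   channel, of [click_waveform]), and `ici_ms`.
#' @export
detect_and_segment <- function(recording, threshold_db = 20,
                               scan_gap_ms = 300, min_sep_ms = 1.5,
                               snippet_ms = 2) {
  stopifnot(inherits(recording, "array_recording"), threshold_db > 0)
  fs <- recording$sample_rate
  geom <- recording$geometry
  chans <- geom$active_channels
  c_mps <- as.numeric(sound_speed_mps(recording$environment))
  span_m <- max(stats::dist(geom$positions[chans, , drop = FALSE]))
  max_tt_s <- span_m / c_mps + 2e-4

  events <- list()
  for (ci in chans) {
    env <- signal_envelope_padded(recording$samples[, ci])
    floor_lvl <- stats::median(env)
    thr <- floor_lvl * 10^(threshold_db / 20)
    idx <- channel_event_peaks(env, thr, round(min_sep_ms / 1e3 * fs))
    if (length(idx)) {
      events[[length(events) + 1]] <- tibble::tibble(
        channel = ci, sample = idx, time_s = (idx - 1) / fs,
        env_peak = env[idx])
    }
  }
  if (!length(events)) return(list())
  ev <- dplyr::arrange(dplyr::bind_rows(events), .data$time_s)

  # coincidence merge: events within the max travel time of a growing
  # cluster belong to the same click
  cluster <- cumsum(c(TRUE, diff(ev$time_s) > max_tt_s))
  ev$click <- cluster

  clicks <- list()
  snippets <- list()
  half <- round(snippet_ms / 2e3 * fs)
  n <- nrow(recording$samples)
  kept <- 0L
  for (cl in unique(ev$click)) {
    sub <- ev[ev$click == cl, ]
    sub <- sub[!duplicated(sub$channel), ]
    kept <- kept + 1L
    snips <- list()
    rls <- rep(NA_real_, geom$n_channels)
    for (r in seq_len(nrow(sub))) {
      ci <- sub$channel[r]
      i0 <- max(1, sub$sample[r] - half)
      i1 <- min(n, sub$sample[r] + half)
      snips[[as.character(ci)]] <- click_waveform(
        recording$samples[i0:i1, ci], fs, channel_id = ci,
        time_offset = (i0 - 1) / fs)
      rls[ci] <- 20 * log10(max(recording$samples[i0:i1, ci]) -
                              min(recording$samples[i0:i1, ci]))
    }
    pk <- sub$channel[which.max(sub$env_peak)]
    clicks[[kept]] <- tibble::tibble(
      click_id = kept, time_s = sub$time_s[which.max(sub$env_peak)],
      peak_channel = pk, n_channels = nrow(sub),
      rl_pp_db = max(rls, na.rm = TRUE))
    clicks[[kept]]$rl_by_channel <- list(rls)
    snippets[[kept]] <- snips
  }
  click_tab <- dplyr::bind_rows(clicks)

  scan_id <- cumsum(c(TRUE, diff(click_tab$time_s) > scan_gap_ms / 1e3))
  lapply(unique(scan_id), function(sid) {
    rows <- which(scan_id == sid)
    tab <- click_tab[rows, ]
    tab$click_id <- seq_len(nrow(tab))
    structure(
      list(clicks = tab, snippets = snippets[rows],
           ici_ms = if (nrow(tab) > 1) diff(tab$time_s) * 1e3 else numeric(0)),
      class = "scan_segment")
  })
}

# indices of local envelope maxima above thr, greedily separated by min_sep
channel_event_peaks <- function(env, thr, min_sep) {
  above <- which(env > thr)
  if (!length(above)) return(integer(0))
  brk <- cumsum(c(TRUE, diff(above) > min_sep))
  vapply(split(above, brk), function(ii) ii[which.max(env[ii])], 0L,
         USE.NAMES = FALSE)
}

#' @export
print.scan_segment <- function(x, ...) {
  cat(sprintf("<scan_segment> %d clicks, ICI %s ms\n", nrow(x$clicks),
              paste(round(x$ici_ms, 1), collapse = ", ")))
  invisible(x)
}

#' Time-difference-of-arrival estimation for one click
#'
#' Cross-correlates each channel's snippet against the reference channel's
#' snippet and refines the correlation peak with parabolic (three-point)
#' sub-sample interpolation. Narrow-band clicks make plain waveform
#' correlation ambiguous to within a carrier cycle, so the lag search is
#' two-stage: a coarse lag from the envelope cross-correlation, then the
#' waveform correlation peak within half a carrier period of it. Snippet
#' time offsets are honoured, so the returned delays are absolute
#' arrival-time differences.
#'
#' @param snippets Named list (by channel index) of [click_waveform]
#'   snippets of one click, as produced by [detect_and_segment()].
#' @param reference_channel Channel the delays are referenced to.
#' @param min_corr Normalized correlation below which a pair is flagged
#'   unreliable.
#' @return A tibble with `channel`, `tdoa_s` (arrival time minus reference
#'   arrival time), `max_corr`, `reliable`.
#' @export
estimate_tdoas <- function(snippets, reference_channel, min_corr = 0.3) {
  chs <- as.integer(names(snippets))
  if (length(chs) < 4) {
    stop("TDOA estimation needs snippets on at least 4 channels",
         call. = FALSE)
  }
  ref_key <- as.character(reference_channel)
  if (!ref_key %in% names(snippets)) {
    stop("reference channel has no snippet", call. = FALSE)
  }
  ref <- snippets[[ref_key]]
  fs <- ref$sample_rate
  # carrier period (samples) from the reference snippet's spectral peak,
  # bounding the refinement window of the waveform correlation
  spec <- Mod(stats::fft(ref$samples))^2
  half <- 2:(length(spec) %/% 2)
  f_pk <- (which.max(spec[half])) * fs / length(spec)
  halfcycle <- max(2, floor(fs / f_pk / 2))
  purrr::map_dfr(chs, function(ci) {
    w <- snippets[[as.character(ci)]]
    coarse <- xcorr_peak(signal_envelope(ref$samples),
                         signal_envelope(w$samples))
    cc <- xcorr_peak(ref$samples, w$samples,
                     window = c(round(coarse$lag) - halfcycle,
                                round(coarse$lag) + halfcycle))
    tdoa <- (w$time_offset - ref$time_offset) + cc$lag / fs
    tibble::tibble(channel = ci, tdoa_s = tdoa, max_corr = cc$corr,
                   reliable = cc$corr >= min_corr)
  })
}

# FFT cross-correlation of b against a; returns the (possibly fractional)
# lag, in samples, by which b is delayed relative to a, and the normalized
# peak correlation. `window` restricts the peak search to a lag interval.
xcorr_peak <- function(a, b, window = NULL) {
  n <- length(a) + length(b) - 1
  nfft <- 2^ceiling(log2(n))
  A <- stats::fft(c(a, numeric(nfft - length(a))))
  B <- stats::fft(c(b, numeric(nfft - length(b))))
  cc <- Re(stats::fft(Conj(A) * B, inverse = TRUE)) / nfft
  # lag k (b delayed by k) lives at index k+1 (mod nfft)
  lags <- c(0:(nfft / 2 - 1), -(nfft / 2):-1)
  search <- if (is.null(window)) seq_along(cc) else
    which(lags >= window[1] & lags <= window[2])
  ipk <- search[which.max(cc[search])]
  # parabolic refinement on the circular neighbourhood
  im <- if (ipk == 1) nfft else ipk - 1
  ip <- if (ipk == nfft) 1 else ipk + 1
  y1 <- cc[im]; y2 <- cc[ipk]; y3 <- cc[ip]
  denom <- y1 - 2 * y2 + y3
  frac <- if (abs(denom) > 0) 0.5 * (y1 - y3) / denom else 0
  frac <- max(min(frac, 0.5), -0.5)
  corr <- y2 / sqrt(sum(a^2) * sum(b^2))
  list(lag = lags[ipk] + frac, corr = corr)
}

#' Localize a source from TDOAs on a vertical line array
#'
#' Nonlinear least-squares fit of a source position to arrival-time
#' differences. A vertical line array cannot resolve azimuth, so the
#' position is parameterized as horizontal range and depth `(x, z)` (with
#' `y = 0`); the fit minimizes the TDOA residuals with a Levenberg-Marquardt
#' solver started from a coarse multi-start grid (5 ranges x 5 depths,
#' lowest-residual start wins). Because the array is over-determined for two
#' unknowns, a localization error can be assessed: the transmission-loss rms
#' error is the rms spread of `20*log10(r) + alpha*r` over
#' leave-one-hydrophone-out sub-solutions, relative to the full-array
#' solution.
#'
#' @param tdoas Tibble from [estimate_tdoas()] (columns `channel`,
#'   `tdoa_s`, optionally `reliable`).
#' @param geometry An [array_geometry].
#' @param sound_speed Sound speed, m/s.
#' @param alpha_db_m Absorption coefficient used in the TL error, dB/m.
#' @param range_starts,depth_starts Multi-start grids, m.
#' @return A `localization_result`: list with `position` (x, y, z),
#'   `range_to_reference`, `ranges` (to every hydrophone), `residual_rms_s`,
#'   `tl_rms_error_db`, `degenerate` flag, and the input `tdoas`.
#' @export
localize <- function(tdoas, geometry, sound_speed, alpha_db_m = 0.04,
                     range_starts = c(5, 10, 20, 40, 60),
                     depth_starts = c(0.5, 2, 4, 6, 10)) {
  stopifnot(inherits(geometry, "array_geometry"))
  if ("reliable" %in% names(tdoas)) tdoas <- tdoas[tdoas$reliable, ]
  tdoas <- tdoas[tdoas$channel %in% geometry$active_channels, ]
  if (nrow(tdoas) < 4) {
    stop("localization failed: fewer than 4 reliable channels",
         call. = FALSE)
  }
  ref <- geometry$reference_channel
  if (!ref %in% tdoas$channel) {
    stop("localization failed: reference channel not among reliable TDOAs",
         call. = FALSE)
  }
  pos <- geometry$positions
  # all-zero TDOAs leave a line array blind to range (source on the
  # broadside symmetry plane at any distance): flag when the largest
  # implied path difference is below ~1 cm
  degenerate <- max(abs(tdoas$tdoa_s)) * sound_speed < 0.01

  fit <- tdoa_ls_fit(tdoas, pos, ref, sound_speed, range_starts,
                     depth_starts)
  if (is.null(fit)) stop("localization failed: solver did not converge",
                         call. = FALSE)
  ranges <- sqrt(colSums((t(pos) - fit$p)^2))
  tl_full <- transmission_loss(ranges[ref], alpha_db_m)

  # leave-one-out sub-solutions over non-reference channels
  loo_ch <- setdiff(tdoas$channel, ref)
  tl_sub <- vapply(loo_ch, function(drop_ch) {
    sub <- tdoas[tdoas$channel != drop_ch, ]
    sfit <- tdoa_ls_fit(sub, pos, ref, sound_speed,
                        range_starts, depth_starts)
    if (is.null(sfit)) return(NA_real_)
    transmission_loss(sqrt(sum((pos[ref, ] - sfit$p)^2)), alpha_db_m)
  }, 0)
  tl_sub <- tl_sub[is.finite(tl_sub)]
  tl_rms_error <- if (length(tl_sub)) {
    sqrt(mean((tl_sub - tl_full)^2))
  } else NA_real_

  structure(
    list(position = fit$p, range_to_reference = ranges[ref],
         ranges = ranges, residual_rms_s = fit$residual_rms,
         tl_rms_error_db = tl_rms_error, degenerate = degenerate,
         tdoas = tdoas, sound_speed = sound_speed,
         alpha_db_m = alpha_db_m),
    class = "localization_result"
  )
}

# Levenberg-Marquardt TDOA fit over (log-range, depth) with multi-start.
tdoa_ls_fit <- function(tdoas, pos, ref, c_mps, range_starts, depth_starts) {
  resid_fn <- function(par) {
    p <- c(exp(par[1]), 0, par[2])
    d <- sqrt(colSums((t(pos) - p)^2))
    (d[tdoas$channel] - d[ref]) / c_mps - tdoas$tdoa_s
  }
  best <- NULL
  for (r0 in range_starts) for (z0 in depth_starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(log(r0), z0), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 100, ftol = 1e-15, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(rss = rss, par = fit$par)
    }
  }
  if (is.null(best)) return(NULL)
  list(p = c(exp(best$par[1]), 0, best$par[2]),
       residual_rms = sqrt(best$rss / nrow(tdoas)))
}

#' @export
print.localization_result <- function(x, ...) {
  cat(sprintf(
    "<localization_result> range %.2f m, depth %.2f m, TL rms error %.2f dB%s\n",
    x$range_to_reference, x$position[3], x$tl_rms_error_db,
    if (x$degenerate) " [degenerate: near-zero TDOAs]" else ""))
  invisible(x)
}

#' Apply the on-axis selection criteria to a scan
#'
#' Evaluates the six on-axis acceptance criteria for every click of a scan:
#' (i) recorded on all six (five) channels; (ii) part of a scan, i.e. the
#' scan holds at least two clicks; (iii) the click of maximum amplitude in
#' the scan; (iv) of maximum amplitude on one of the four (three) middle
#' hydrophones; (v) the direct path stronger than any trailing surface or
#' bottom reflection within `echo_window_ms`; (vi) at most one click per
#' scan accepted. Clicks belonging to a buzz (preceding inter-click interval
#' below `buzz_ici_ms`) are excluded before the criteria are applied.
#'
#' @param scan A `scan_segment` from [detect_and_segment()].
#' @param recording The `array_recording` the scan came from (needed for the
#'   trailing-echo check).
#' @param mode `"six_channel"` or `"five_channel"` (the latter reflects the
#'   configuration with hydrophone 3 missing and relaxes criteria i/iv
#'   accordingly).
#' @param echo_window_ms Trailing window scanned for reflections, ms.
#' @param buzz_ici_ms Inter-click interval below which clicks are treated as
#'   buzz clicks and excluded, ms.
#' @return A tibble with one row per click: per-criterion logicals
#'   `crit_i` .. `crit_vi`, `accepted` (the AND of all six), `is_buzz` and
#'   `reject_reason`.
#' @export
select_on_axis <- function(scan, recording,
                           mode = c("six_channel", "five_channel"),
                           echo_window_ms = 20, buzz_ici_ms = 13) {
  stopifnot(inherits(scan, "scan_segment"),
            inherits(recording, "array_recording"))
  mode <- match.arg(mode)
  geom <- recording$geometry
  required_n <- if (mode == "six_channel") 6L else 5L
  middle <- middle_channels(geom, mode)
  tab <- scan$clicks
  nclk <- nrow(tab)

  is_buzz <- c(FALSE, scan$ici_ms < buzz_ici_ms)[seq_len(nclk)]
  eligible <- !is_buzz

  rl <- tab$rl_pp_db
  rl_max <- max(rl[eligible], -Inf)
  crit_i <- tab$n_channels >= required_n
  crit_ii <- rep(sum(eligible) >= 2, nclk)
  crit_iii <- eligible & rl == rl_max
  crit_iv <- tab$peak_channel %in% middle
  crit_v <- vapply(seq_len(nclk), function(k) {
    !trailing_echo_stronger(recording, tab$time_s[k], tab$peak_channel[k],
                            echo_window_ms)
  }, TRUE)

  pass_to_v <- eligible & crit_i & crit_ii & crit_iii & crit_iv & crit_v
  crit_vi <- rep(FALSE, nclk)
  if (any(pass_to_v)) {
    winner <- which(pass_to_v)[which.max(rl[pass_to_v])]
    crit_vi[winner] <- TRUE
  }
  accepted <- pass_to_v & crit_vi

  reason <- dplyr::case_when(
    is_buzz ~ "buzz",
    !crit_i ~ "not on all required channels",
    !crit_ii ~ "not part of a scan",
    !crit_iii ~ "not scan maximum",
    !crit_iv ~ "maximum on outer hydrophone",
    !crit_v ~ "trailing reflection stronger than direct path",
    !crit_vi ~ "another click accepted in scan",
    TRUE ~ ""
  )
  tibble::tibble(
    click_id = tab$click_id, time_s = tab$time_s,
    peak_channel = tab$peak_channel, rl_pp_db = rl,
    is_buzz = is_buzz,
    crit_i = crit_i, crit_ii = crit_ii, crit_iii = crit_iii,
    crit_iv = crit_iv, crit_v = crit_v, crit_vi = crit_vi,
    accepted = accepted, reject_reason = reason
  )
}

# middle hydrophones: all but the outermost active channels (four of six;
# three of five when one mid-array channel is missing)
middle_channels <- function(geometry, mode) {
  act <- geometry$active_channels
  z <- geometry$positions[act, "z"]
  act[z > min(z) & z < max(z)]
}

# TRUE if any envelope value in (t + 0.3 ms, t + window] on the given
# channel exceeds the direct-path peak. Bottom/surface reflections arrive
# within a few ms of the direct path at these recording geometries, well
# inside the window, while genuine non-buzz clicks are tens of ms apart.
trailing_echo_stronger <- function(recording, t_click, channel,
                                   echo_window_ms) {
  fs <- recording$sample_rate
  n <- nrow(recording$samples)
  i0 <- round(t_click * fs) + 1
  direct <- max(signal_envelope_padded(
    recording$samples[max(1, i0 - 250):min(n, i0 + 250), channel]))
  j0 <- min(n, i0 + round(0.3e-3 * fs))
  j1 <- min(n, i0 + round(echo_window_ms / 1e3 * fs))
  if (j1 <= j0) return(FALSE)
  seg <- signal_envelope_padded(recording$samples[j0:j1, channel])
  any(seg > direct)
}
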