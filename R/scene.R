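#' Vertical hydrophone-array geometry
#'
#' Hydrophone positions in a right-handed frame with z positive downward
#' from the surface and the array on the z axis. The default mirrors the
#' deployed line array: six elements, 0.75 m spacing except 1.5 m between
#' the two topmost hydrophones, top element at `top_depth`.
#'
#' @param hydrophone_depths Depths of the hydrophones, m (top first). The
#'   default is the Canadian deployment (top element 2 m down).
#' @param active_channels Indices of channels in use. Dropping a channel
#'   (e.g. `active_channels = c(1, 2, 4, 5, 6)`) reproduces the five-channel
#'   configuration used after one mid-array element failed.
#' @param reference_channel Channel used as the time reference for TDOAs.
#' @return An `array_geometry` object with a `positions` matrix (n x 3).
#' @export
array_geometry <- function(hydrophone_depths = c(2, 3.5, 4.25, 5, 5.75, 6.5),
                           active_channels = seq_along(hydrophone_depths),
                           reference_channel = active_channels[1]) {
  stopifnot(length(hydrophone_depths) >= 2,
            !anyDuplicated(hydrophone_depths),
            all(active_channels %in% seq_along(hydrophone_depths)),
            reference_channel %in% active_channels)
  if (length(active_channels) < 4) {
    stop("at least 4 active channels are required for localization",
         call. = FALSE)
  }
  pos <- cbind(x = 0, y = 0, z = as.numeric(hydrophone_depths))
  structure(
    list(positions = pos, active_channels = sort(active_channels),
         reference_channel = reference_channel,
         n_channels = nrow(pos)),
    class = "array_geometry"
  )
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf("<array_geometry> %d hydrophones at z = %s m, %d active, ref = %d\n",
              x$n_channels, paste(x$positions[, "z"], collapse = ", "),
              length(x$active_channels), x$reference_channel))
  invisible(x)
}

#' Click source specification
#'
#' Ground-truth description of one echolocating source for the scene
#' simulator.
#'
#' @param position Length-3 numeric, source position (x, y, z) in m; x must
#'   be positive (sources sit in front of the array plane).
#' @param aim_at Either a length-3 point the acoustic axis points at, or a
#'   channel index (the source aims straight at that hydrophone).
#' @param fc_khz Centroid frequency of the emitted click, kHz.
#' @param duration_10db_us -10 dB click duration, us.
#' @param sl_pp_db Source level, dB re 1 uPa peak-peak at 1 m.
#' @param aperture_cm Equivalent piston aperture diameter, cm.
#' @param ici_ms Inter-click intervals of the emitted train, ms; a train of
#'   `length(ici_ms) + 1` clicks is rendered.
#' @return A `click_source_spec` object.
#' @export
click_source_spec <- function(position, aim_at = 3L, fc_khz = 137,
                              duration_10db_us = 104, sl_pp_db = 183,
                              aperture_cm = 10,
                              ici_ms = rep(60, 5)) {
  stopifnot(length(position) == 3, fc_khz > 0, duration_10db_us > 0,
            aperture_cm > 0, all(ici_ms > 0))
  if (position[1] <= 0) {
    stop("source must lie at positive x (in front of the array axis)",
         call. = FALSE)
  }
  structure(
    list(position = as.numeric(position), aim_at = aim_at, fc_khz = fc_khz,
         duration_10db_us = duration_10db_us, sl_pp_db = sl_pp_db,
         aperture_cm = aperture_cm, ici_ms = as.numeric(ici_ms)),
    class = "click_source_spec"
  )
}

#' Scene configuration for the array simulator
#'
#' @param geometry An [array_geometry].
#' @param environment An [environment_profile].
#' @param sources A list of [click_source_spec] objects (a single spec is
#'   accepted).
#' @param noise_spectral_level Per-channel white ambient noise spectral
#'   level, dB re 1 uPa^2/Hz; `-Inf` for a noiseless scene.
#' @param sample_rate Sampling rate, Hz (default 500 kHz).
#' @param seed Integer seed; mandatory so every rendered scene is
#'   reproducible.
#' @param quantize Apply 16-bit quantization after normalizing the scene
#'   peak to -6 dBFS (emulating the recording chain ADC)? Default `TRUE`.
#' @return A `scene_config` object.
#' @export
scene_config <- function(geometry, environment, sources,
                         noise_spectral_level = 40, sample_rate = 5e5,
                         seed, quantize = TRUE) {
  if (inherits(sources, "click_source_spec")) sources <- list(sources)
  stopifnot(inherits(geometry, "array_geometry"),
            inherits(environment, "environment_profile"),
            all(vapply(sources, inherits, TRUE, "click_source_spec")))
  if (missing(seed)) stop("a seed is mandatory for scene rendering",
                          call. = FALSE)
  fcs <- vapply(sources, `[[`, 0, "fc_khz")
  # margin above Nyquist so the upper spectral skirt of a narrow-band click
  # is fully sampled (the emulated recording chain runs 500 kHz for
  # ~137 kHz clicks, a factor 3.65)
  if (sample_rate < 3 * max(fcs) * 1e3) {
    stop("sample_rate must be at least 3x the highest source fc",
         call. = FALSE)
  }
  structure(
    list(geometry = geometry, environment = environment, sources = sources,
         noise_spectral_level = noise_spectral_level,
         sample_rate = sample_rate, seed = as.integer(seed),
         quantize = quantize),
    class = "scene_config"
  )
}

# Resolve the point a source aims at and the resulting acoustic axis.
source_axis <- function(src, geometry) {
  target <- if (length(src$aim_at) == 1) {
    geometry$positions[as.integer(src$aim_at), ]
  } else {
    as.numeric(src$aim_at)
  }
  v <- target - src$position
  v / sqrt(sum(v^2))
}

# Off-axis angle (deg) from the source acoustic axis to each hydrophone.
offaxis_angles_to_channels <- function(src, geometry) {
  axis <- source_axis(src, geometry)
  vapply(seq_len(geometry$n_channels), function(i) {
    v <- geometry$positions[i, ] - src$position
    v <- v / sqrt(sum(v^2))
    acos(pmin(1, pmax(-1, sum(v * axis)))) * 180 / pi
  }, 0)
}

#' Render a six-channel array recording of a synthetic scene
#'
#' Renders each source's click train into every channel: the unit pip is
#' scaled so its peak-peak level at the 1 m reference equals the source
#' level, filtered by the piston transfer function at the channel's off-axis
#' angle, propagated (delay, spherical spreading, per-bin absorption) over
#' the source-to-hydrophone distance, and summed into the channel. White
#' Gaussian noise at the configured spectral level is added per channel, and
#' the scene is optionally passed through a 16-bit ADC emulation (peak at
#' -6 dBFS). A ground-truth table travels with the recording.
#'
#' @param scene A [scene_config].
#' @param surface_echo Optional list `list(delay_ms =, level_db =)`;
#'   injects, for every rendered click, a delayed copy attenuated by
#'   `level_db` (dB re the direct path) on every channel. Used to exercise
#'   the echo-rejection criterion.
#' @return An `array_recording`: list with `samples` (n x channels matrix,
#'   uPa), `sample_rate`, `geometry`, `environment`, and `ground_truth`
#'   (tibble: one row per click x channel with true times, ranges, angles
#'   and emitted parameters; `onaxis_channel` marks the channel closest to
#'   the acoustic axis).
#' @export
render_array_recording <- function(scene, surface_echo = NULL) {
  stopifnot(inherits(scene, "scene_config"))
  geom <- scene$geometry
  env <- scene$environment
  fs <- scene$sample_rate
  c_mps <- as.numeric(sound_speed_mps(env))

  max_range <- 0
  click_times <- list()
  for (si in seq_along(scene$sources)) {
    src <- scene$sources[[si]]
    tt <- c(0, cumsum(src$ici_ms)) / 1e3 + 0.05
    click_times[[si]] <- tt
    rr <- sqrt(colSums((t(geom$positions) - src$position)^2))
    max_range <- max(max_range, max(rr))
  }
  t_end <- max(vapply(click_times, max, 0)) + max_range / c_mps + 0.03
  n <- ceiling(t_end * fs)
  sig <- matrix(0, nrow = n, ncol = geom$n_channels)

  gt <- list()
  for (si in seq_along(scene$sources)) {
    src <- scene$sources[[si]]
    angles <- offaxis_angles_to_channels(src, geom)
    ranges <- sqrt(colSums((t(geom$positions) - src$position)^2))
    onaxis_channel <- geom$active_channels[
      which.min(angles[geom$active_channels])]
    base <- generate_nbhf_waveform(src$fc_khz, src$duration_10db_us, fs)
    pp0 <- max(base$samples) - min(base$samples)
    scale <- 10^(src$sl_pp_db / 20) / pp0
    src_wave <- click_waveform(base$samples * scale, fs)
    n_half <- (length(base$samples) - 1) / 2

    for (ci in geom$active_channels) {
      w <- apply_piston_offaxis(src_wave, angles[ci], src$aperture_cm, c_mps)
      w <- propagate_click(w, ranges[ci], env)
      for (k in seq_along(click_times[[si]])) {
        t0 <- click_times[[si]][k]
        idx0 <- round(t0 * fs) + round(w$time_offset * fs) - n_half
        idx <- idx0:(idx0 + length(w$samples) - 1)
        keep <- idx >= 1 & idx <= n
        sig[idx[keep], ci] <- sig[idx[keep], ci] + w$samples[keep]
        if (!is.null(surface_echo)) {
          eidx <- idx + round(surface_echo$delay_ms / 1e3 * fs)
          ekeep <- eidx >= 1 & eidx <= n
          sig[eidx[ekeep], ci] <- sig[eidx[ekeep], ci] +
            w$samples[ekeep] * 10^(surface_echo$level_db / 20)
        }
      }
    }

    for (k in seq_along(click_times[[si]])) {
      gt[[length(gt) + 1]] <- tibble::tibble(
        source_id = si, click_id = k,
        emit_time_s = click_times[[si]][k],
        channel = seq_len(geom$n_channels),
        arrival_time_s = click_times[[si]][k] + ranges / c_mps,
        range_m = ranges, angle_deg = angles,
        onaxis_channel = onaxis_channel,
        fc_khz = src$fc_khz, duration_10db_us = src$duration_10db_us,
        sl_pp_db = src$sl_pp_db, aperture_cm = src$aperture_cm,
        pos_x = src$position[1], pos_y = src$position[2],
        pos_z = src$position[3])
    }
  }

  set.seed(scene$seed)
  if (is.finite(scene$noise_spectral_level)) {
    sd_noise <- sqrt(10^(scene$noise_spectral_level / 10) * fs / 2)
    sig <- sig + matrix(stats::rnorm(length(sig), sd = sd_noise),
                        nrow = n)
  }

  upa_per_count <- NULL
  if (scene$quantize) {
    peak <- max(abs(sig))
    if (peak > 0) {
      full_scale <- peak * 2  # peak sits at -6 dBFS
      q <- round(sig / full_scale * 32767)
      q <- pmin(pmax(q, -32768), 32767)
      upa_per_count <- full_scale / 32767
      sig <- q * upa_per_count
    }
  }

  structure(
    list(samples = sig, sample_rate = fs, geometry = geom,
         environment = env,
         noise_spectral_level = scene$noise_spectral_level,
         upa_per_count = upa_per_count,
         ground_truth = dplyr::bind_rows(gt)),
    class = "array_recording"
  )
}

#' @export
print.array_recording <- function(x, ...) {
  cat(sprintf("<array_recording> %d channels x %.3f s @ %g kHz, %d true clicks\n",
              ncol(x$samples), nrow(x$samples) / x$sample_rate,
              x$sample_rate / 1e3,
              length(unique(paste(x$ground_truth$source_id,
                                  x$ground_truth$click_id)))))
  invisible(x)
}

# Population parameter distributions (mean, sd, range) for the three
# recorded porpoise groups: Dall's and harbour porpoise off British
# Columbia, and harbour porpoise in Danish waters. Aperture is the single
# reported equivalent-aperture diameter per group.
population_table <- function() {
  tibble::tribble(
    ~population,      ~fc_mean, ~fc_sd, ~fc_lo, ~fc_hi,
      ~dur_mean, ~dur_sd, ~dur_lo, ~dur_hi,
      ~sl_mean, ~sl_sd, ~sl_lo, ~sl_hi, ~aperture_cm,
    "bc_dalls",        137, 3, 121, 147,  104, 37, 53, 251,
      183, 7, 153, 203, 10,
    "bc_harbour",      141, 2, 138, 148,   88, 29, 48, 189,
      178, 4, 170, 189, 12,
    "danish_harbour",  136, 3, 126, 144,   54,  8, 35,  98,
      189, 5, 169, 199, 10
  )
}

# Truncated-normal draws by rejection; the truncation bounds are the
# observed parameter ranges. Asymmetric bounds bias the truncated mean away
# from the reported mean, so the underlying location is moment-matched: it
# is solved so the truncated distribution's mean equals the reported mean
# (the reported statistics describe the observed, i.e. truncated, data).
rtruncnorm <- function(n, mean, sd, lo, hi) {
  trunc_mean <- function(mu) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    z <- stats::pnorm(b) - stats::pnorm(a)
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
  }
  mu <- stats::uniroot(function(m) trunc_mean(m) - mean,
                       interval = c(mean - 2 * sd, mean + 2 * sd),
                       tol = 1e-10)$root
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 10, mu, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Draw click source parameters for a porpoise population
#'
#' Draws centroid frequency, -10 dB duration and peak-peak source level from
#' independent truncated normal distributions whose means, standard
#' deviations and truncation ranges are the measured on-axis click statistics
#' of the named population. The equivalent aperture is the population's
#' single reported value.
#'
#' @param population One of `"bc_dalls"`, `"bc_harbour"`,
#'   `"danish_harbour"`.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return A tibble with columns `population`, `fc_khz`, `duration_10db_us`,
#'   `sl_pp_db`, `aperture_cm`.
#' @examples
#' sample_population_parameters("bc_dalls", 5, seed = 1)
#' @export
sample_population_parameters <- function(population, n, seed) {
  stopifnot(n >= 1)
  tab <- population_table()
  row <- tab[tab$population == population, ]
  if (nrow(row) != 1) {
    stop("unknown population: ", population,
         " (expected one of ", paste(tab$population, collapse = ", "), ")",
         call. = FALSE)
  }
  set.seed(seed)
  tibble::tibble(
    population = population,
    fc_khz = rtruncnorm(n, row$fc_mean, row$fc_sd, row$fc_lo, row$fc_hi),
    duration_10db_us = rtruncnorm(n, row$dur_mean, row$dur_sd, row$dur_lo,
                                  row$dur_hi),
    sl_pp_db = rtruncnorm(n, row$sl_mean, row$sl_sd, row$sl_lo, row$sl_hi),
    aperture_cm = row$aperture_cm
  )
}
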