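#' Hearing audiogram
#'
#' A hearing-threshold curve (dB re 1 uPa versus kHz) used, inverted, as a
#' reception filter. [default_audiogram()] ships a synthetic U-shaped
#' harbour-porpoise-style curve — best sensitivity at 100 kHz, thresholds
#' rising by 30 dB at 160 kHz and 40 dB at 16 kHz — standing in for
#' published behavioural audiograms, which are not distributed with the
#' package. Any measured curve can be supplied as a two-column table
#' (kHz, dB).
#'
#' @param frequencies_khz Strictly increasing frequencies, kHz; at least 4
#'   points spanning `[16, 180]` kHz.
#' @param thresholds_db Hearing thresholds, dB re 1 uPa.
#' @param name Label for the curve.
#' @return An `audiogram` object (a tibble with attributes).
#' @export
audiogram <- function(frequencies_khz, thresholds_db, name = "audiogram") {
  stopifnot(length(frequencies_khz) == length(thresholds_db),
            length(frequencies_khz) >= 4,
            all(diff(frequencies_khz) > 0))
  if (frequencies_khz[1] > 16 ||
      frequencies_khz[length(frequencies_khz)] < 180) {
    stop("audiogram must span at least [16, 180] kHz", call. = FALSE)
  }
  structure(
    tibble::tibble(freq_khz = frequencies_khz, threshold_db = thresholds_db),
    class = c("audiogram", "tbl_df", "tbl", "data.frame"),
    name = name
  )
}

#' @rdname audiogram
#' @export
default_audiogram <- function() {
  audiogram(
    frequencies_khz = c(16, 32, 63, 100, 125, 140, 160, 180),
    thresholds_db = c(80, 60, 45, 40, 42, 48, 70, 90),
    name = "synthetic harbour-porpoise-style audiogram"
  )
}

# audiogram threshold interpolated linearly in dB over log-frequency,
# clamped to the edge values outside the tabulated support
audiogram_threshold <- function(aud, f_khz) {
  lf <- log10(pmax(f_khz, 1e-6))
  stats::approx(log10(aud$freq_khz), aud$threshold_db, xout = lf,
                rule = 2)$y
}

#' Filter a click through an inverted audiogram
#'
#' Emulates reception by an animal with the given audiogram: the click
#' spectrum is multiplied by a zero-phase filter whose magnitude response is
#' the inverted, normalized hearing curve — 0 dB at the frequency of best
#' hearing, `-(threshold(f) - min threshold)` elsewhere. The interpolation
#' is linear in dB over log frequency. The filtered click can then be
#' re-parameterized with [click_parameters()]; with a realistic
#' porpoise-style audiogram (steep loss above ~140 kHz) this pulls centroid
#' frequencies downward.
#'
#' @param w A [click_waveform]; its centroid frequency must lie inside the
#'   audiogram's tabulated support.
#' @param aud An [audiogram].
#' @param squared Apply the magnitude response squared (used to verify the
#'   cascade property filter-twice == squared-once). Default `FALSE`.
#' @return The filtered [click_waveform].
#' @export
audiogram_filter <- function(w, aud, squared = FALSE) {
  stopifnot(inherits(w, "click_waveform"), inherits(aud, "audiogram"))
  fc <- compute_spectral_metrics(w)$f_centroid_khz
  if (fc < aud$freq_khz[1] || fc > aud$freq_khz[nrow(aud)]) {
    stop("click energy band outside audiogram support", call. = FALSE)
  }
  n <- length(w$samples)
  f <- abs(fft_bin_freqs(n, w$sample_rate)) / 1e3
  gain_db <- -(audiogram_threshold(aud, f) - min(aud$threshold_db))
  if (squared) gain_db <- 2 * gain_db
  g <- 10^(gain_db / 20)
  out <- Re(stats::fft(stats::fft(w$samples) * g, inverse = TRUE)) / n
  click_waveform(out, w$sample_rate, w$channel_id, w$time_offset)
}

#' ROC-optimal centroid-frequency criterion
#'
#' Scans candidate thresholds on a 0.1 kHz grid and selects the one
#' maximizing overall proportion correct for separating two
#' centroid-frequency samples (equivalently, the ROC operating point
#' minimizing total misclassification at equal weight). Ties are broken
#' toward the midpoint of the tied thresholds.
#'
#' @param fc_a,fc_b Centroid-frequency samples (kHz) for the two classes;
#'   class A is the one classified below the criterion.
#' @return A `roc_criterion` object: `criterion_khz` (0.1 kHz resolution),
#'   `criterion_int_khz` (nearest integer), `accuracy` (proportion correct
#'   at the criterion), and `direction` (`"a_below"` or `"a_above"`).
#' @export
roc_criterion <- function(fc_a, fc_b) {
  fc_a <- as.numeric(fc_a); fc_b <- as.numeric(fc_b)
  stopifnot(length(fc_a) > 0, length(fc_b) > 0)
  if (length(unique(c(fc_a, fc_b))) == 1) {
    stop("degenerate ROC: both samples are identical constants",
         call. = FALSE)
  }
  grid <- seq(floor(min(c(fc_a, fc_b)) * 10) / 10,
              ceiling(max(c(fc_a, fc_b)) * 10) / 10, by = 0.1)
  n_a <- length(fc_a); n_b <- length(fc_b)
  acc_below <- vapply(grid, function(t) {
    (sum(fc_a < t) + sum(fc_b >= t)) / (n_a + n_b)
  }, 0)
  acc_above <- 1 - acc_below  # swapping class labels inverts the rule
  direction <- if (max(acc_below) >= max(acc_above)) "a_below" else "a_above"
  acc <- if (direction == "a_below") acc_below else acc_above
  best <- which(acc == max(acc))
  crit <- round(mean(grid[best]), 1)
  structure(
    list(criterion_khz = crit,
         criterion_int_khz = round(crit),
         accuracy = max(acc), direction = direction,
         n_a = n_a, n_b = n_b),
    class = "roc_criterion"
  )
}

#' @export
print.roc_criterion <- function(x, ...) {
  cat(sprintf(
    "<roc_criterion> %.1f kHz (integer %d kHz), accuracy %.1f%% (class A %s)\n",
    x$criterion_khz, x$criterion_int_khz, 100 * x$accuracy,
    if (x$direction == "a_below") "below criterion" else "above criterion"))
  invisible(x)
}

#' Monte Carlo species discrimination by mean centroid frequency
#'
#' Draws `n_sets` click sets of each size from each species' click dataset
#' (a 1:5 on-axis : off-axis mixture when built with
#' [simulate_click_dataset()]), classifies every set by whether its mean
#' centroid frequency falls below (species A) or above (species B) the
#' criterion, and reports overall percent correct per set size, averaged
#' over `n_repeats` repeats with the standard error of the mean.
#'
#' Sets are drawn without replacement within a set when the dataset is
#' large enough; otherwise sampling falls back to with-replacement and the
#' result is flagged.
#'
#' @param pop_a,pop_b Click datasets: tibbles with an `f_centroid_khz`
#'   column (plain numeric vectors also accepted). Species A is the
#'   below-criterion class.
#' @param criterion_khz Fixed classification criterion, kHz (chosen before
#'   the draws, e.g. by [roc_criterion()]).
#' @param set_sizes Set sizes to evaluate.
#' @param n_sets Sets per species per repeat.
#' @param n_repeats Number of repeats.
#' @param seed Integer seed.
#' @return A `mc_discrimination` tibble: `set_size`, `percent_correct`
#'   (mean over repeats), `sem`, `n_sets`, `n_repeats`; attributes carry
#'   the criterion and the with-replacement flag. Methods: [tidy()],
#'   [autoplot()].
#' @export
monte_carlo_discrimination <- function(pop_a, pop_b, criterion_khz,
                                       set_sizes = c(1, 2, 4, 8, 16, 32),
                                       n_sets = 100, n_repeats = 10, seed) {
  fa <- if (is.data.frame(pop_a)) pop_a$f_centroid_khz else as.numeric(pop_a)
  fb <- if (is.data.frame(pop_b)) pop_b$f_centroid_khz else as.numeric(pop_b)
  stopifnot(length(fa) > 0, length(fb) > 0)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  set.seed(seed)
  replacement_used <- any(set_sizes > length(fa)) ||
    any(set_sizes > length(fb))
  if (replacement_used) {
    warning("dataset smaller than a requested set size; ",
            "sampling with replacement")
  }

  res <- purrr::map_dfr(seq_len(n_repeats), function(rep_i) {
    purrr::map_dfr(set_sizes, function(N) {
      repl_a <- N > length(fa); repl_b <- N > length(fb)
      mean_a <- vapply(seq_len(n_sets), function(i) {
        mean(sample(fa, N, replace = repl_a))
      }, 0)
      mean_b <- vapply(seq_len(n_sets), function(i) {
        mean(sample(fb, N, replace = repl_b))
      }, 0)
      correct <- sum(mean_a < criterion_khz) + sum(mean_b >= criterion_khz)
      tibble::tibble(repeat_id = rep_i, set_size = N,
                     percent_correct = 100 * correct / (2 * n_sets))
    })
  })

  out <- res |>
    dplyr::group_by(.data$set_size) |>
    dplyr::summarise(
      sem = stats::sd(.data$percent_correct) / sqrt(n_repeats),
      percent_correct = mean(.data$percent_correct),
      .groups = "drop") |>
    dplyr::mutate(n_sets = n_sets, n_repeats = n_repeats) |>
    dplyr::select("set_size", "percent_correct", "sem", "n_sets",
                  "n_repeats")
  structure(out,
            class = c("mc_discrimination", class(out)),
            criterion_khz = criterion_khz,
            replacement_used = replacement_used,
            per_repeat = res)
}

#' Simulate a click dataset with piston-model off-axis variants
#'
#' Builds the species click dataset used for discrimination analyses: for
#' each drawn source parameter set ([sample_population_parameters()]) the
#' on-axis click is synthesized and parameterized, and the five clicks
#' simultaneously received on the other hydrophones are emulated by
#' piston-filtering the same click at the channel off-axis angles of a
#' source at `range_m` aiming straight at hydrophone `aim_channel` — one
#' on-axis click for every five off-axis clicks. Optionally every click is
#' first passed through an inverted [audiogram] filter before
#' re-parameterization.
#'
#' @param population Population name, see [sample_population_parameters()].
#' @param n_onaxis Number of on-axis clicks (total rows are 6x this).
#' @param seed Integer seed.
#' @param geometry An [array_geometry].
#' @param env An [environment_profile].
#' @param range_m Source range used for the off-axis geometry, m.
#' @param aim_channel Hydrophone the source aims at.
#' @param audiogram Optional [audiogram] applied to every click before
#'   parameter extraction.
#' @return A tibble: `population`, `click`, `channel`, `is_onaxis`,
#'   `angle_deg`, plus all [click_parameters()] columns.
#' @export
simulate_click_dataset <- function(population, n_onaxis, seed,
                                   geometry = array_geometry(),
                                   env = environment_profile(9.2, 33.9),
                                   range_m = 30, aim_channel = 3L,
                                   audiogram = NULL) {
  pars <- sample_population_parameters(population, n_onaxis, seed)
  c_mps <- as.numeric(sound_speed_mps(env))
  src_pos <- c(range_m, 0, geometry$positions[aim_channel, "z"])
  src <- click_source_spec(src_pos, aim_at = aim_channel)
  angles <- offaxis_angles_to_channels(src, geometry)[geometry$active_channels]
  chans <- geometry$active_channels

  purrr::map_dfr(seq_len(n_onaxis), function(i) {
    w <- generate_nbhf_waveform(pars$fc_khz[i], pars$duration_10db_us[i])
    purrr::map_dfr(seq_along(chans), function(j) {
      ang <- if (chans[j] == aim_channel) 0 else angles[j]
      wj <- apply_piston_offaxis(w, ang, pars$aperture_cm[i], c_mps)
      if (!is.null(audiogram)) wj <- audiogram_filter(wj, audiogram)
      dplyr::bind_cols(
        tibble::tibble(population = population, click = i,
                       channel = chans[j],
                       is_onaxis = chans[j] == aim_channel,
                       angle_deg = ang),
        click_parameters(wj))
    })
  })
}

#' Source-level trend diagnostics
#'
#' Two checks that observed source-level differences between groups are not
#' artifacts of recording range or click repetition rate: (1) an ordinary
#' least-squares regression of source level on recording range per group,
#' and (2) mean +- sd of source level per inter-click-interval band, with
#' band edges 0-40, 40-60, 60-80, 80-100, 100-150, 150-200 ms (left-closed,
#' right-open).
#'
#' @param clicks Tibble of accepted clicks with columns `sl_pp_db`,
#'   `range_m`, `ici_ms`, and a grouping column.
#' @param group Name of the grouping column (default `"population"`).
#' @return A list of two tibbles: `regression` (`group`, `intercept`,
#'   `slope`, `r_squared`, `n`) and `ici_bands` (`group`, `band`, `n`,
#'   `mean_sl_db`, `sd_sl_db`; sd is `NA` for bands with fewer than 2
#'   clicks).
#' @export
sl_trend_diagnostics <- function(clicks, group = "population") {
  stopifnot(all(c("sl_pp_db", "range_m", "ici_ms", group) %in%
                  names(clicks)))
  grp <- rlang::sym(group)

  regression <- clicks |>
    dplyr::group_by(!!grp) |>
    dplyr::group_modify(function(d, key) {
      fit <- stats::lm(sl_pp_db ~ range_m, data = d)
      co <- unname(stats::coef(fit))
      tibble::tibble(
        intercept = co[1], slope = co[2],
        r_squared = suppressWarnings(summary(fit)$r.squared), n = nrow(d))
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(group = !!grp)

  edges <- c(0, 40, 60, 80, 100, 150, 200)
  labels <- paste0(utils::head(edges, -1), "-", edges[-1], " ms")
  ici_bands <- clicks |>
    dplyr::mutate(band = cut(.data$ici_ms, breaks = edges, labels = labels,
                             right = FALSE)) |>
    dplyr::filter(!is.na(.data$band)) |>
    dplyr::group_by(!!grp, .data$band) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_sl_db = mean(.data$sl_pp_db),
      sd_sl_db = ifelse(dplyr::n() >= 2, stats::sd(.data$sl_pp_db),
                        NA_real_),
      .groups = "drop") |>
    dplyr::rename(group = !!grp)

  list(regression = regression, ici_bands = ici_bands)
}
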