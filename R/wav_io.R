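#' Write a multichannel recording as a RIFF PCM WAV file
#'
#' Writes 16-bit PCM with the scene peak placed at -6 dBFS (no clipping)
#' and stores the exact count-to-microPascal calibration scale — together
#' with the ground-truth table, if present — in a JSON sidecar
#' (`<path>.json`) so a write/read round trip is bit-identical in counts
#' and exact in pressure.
#'
#' @param recording An `array_recording`.
#' @param path Output path (`.wav`).
#' @param sidecar Write the JSON calibration/ground-truth sidecar? Default
#'   `TRUE`.
#' @return `path`, invisibly.
#' @export
write_multichannel_wav <- function(recording, path, sidecar = TRUE) {
  stopifnot(inherits(recording, "array_recording"))
  sig <- recording$samples
  fs <- recording$sample_rate
  n_ch <- ncol(sig)
  # reuse the recording's own ADC scale when it has one (render-time
  # quantization), so counts survive a write/read round trip unchanged
  full_scale <- if (!is.null(recording$upa_per_count)) {
    recording$upa_per_count * 32767
  } else {
    peak <- max(abs(sig))
    if (peak > 0) peak * 2 else 1
  }
  counts <- pmin(pmax(round(sig / full_scale * 32767), -32768L), 32767L)

  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- length(counts) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * n_ch * 2), con, size = 4, endian = "little")
  writeBin(as.integer(n_ch * 2), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(as.integer(t(counts)), con, size = 2, endian = "little")

  if (sidecar) {
    meta <- list(
      upa_per_count = full_scale / 32767,
      sample_rate = fs,
      n_channels = n_ch,
      hydrophone_depths = recording$geometry$positions[, "z"],
      active_channels = recording$geometry$active_channels,
      reference_channel = recording$geometry$reference_channel,
      environment = unclass(recording$environment),
      noise_spectral_level = recording$noise_spectral_level
    )
    if (!is.null(recording$ground_truth)) {
      meta$ground_truth <- recording$ground_truth
    }
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a multichannel RIFF PCM WAV file
#'
#' Reads 16-bit PCM WAV and calibrates the counts to microPascal. If the
#' JSON sidecar written by [write_multichannel_wav()] is present its exact
#' scale (and geometry/environment/ground truth) are used; otherwise the
#' hydrophone sensitivity chain is applied: a full-scale count maps to
#' `full_scale_volts`, and pressure is
#' `volts / 10^((sensitivity_db + gain_db)/20)` — with the default
#' -221 dB re 1V/uPa sensitivity and unity gain, a full-scale sample is
#' 221 dB re 1 uPa.
#'
#' @param path Path to the WAV file.
#' @param geometry Optional [array_geometry]; must match the channel count.
#' @param environment Optional [environment_profile] (used when no sidecar
#'   is present).
#' @param sensitivity_db Hydrophone sensitivity, dB re 1 V/uPa.
#' @param gain_db Recording-chain gain, dB.
#' @param full_scale_volts Voltage at full-scale counts.
#' @return An `array_recording`.
#' @export
read_multichannel_wav <- function(path, geometry = NULL, environment = NULL,
                                  sensitivity_db = -221, gain_db = 0,
                                  full_scale_volts = 1) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_tag <- function() {
    raw4 <- readBin(con, "raw", 4)
    if (length(raw4) < 4) return(NA_character_)
    if (any(raw4 == as.raw(0))) return("")
    rawToChar(raw4)
  }
  if (!identical(read_tag(), "RIFF")) stop("not a RIFF file", call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(read_tag(), "WAVE")) stop("not a WAVE file", call. = FALSE)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- read_tag()
    if (is.na(id)) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, size = 2,
                               endian = "little"),
        n_channels = readBin(con, "integer", 1, size = 2,
                             endian = "little"),
        sample_rate = readBin(con, "integer", 1, size = 4,
                              endian = "little"))
      readBin(con, "raw", sz - 8)
    } else if (id == "data") {
      data_raw <- readBin(con, "integer", sz / 2, size = 2,
                          endian = "little")
      break
    } else {
      readBin(con, "raw", sz)
    }
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("malformed WAV: missing fmt or data chunk", call. = FALSE)
  }
  if (fmt$audio_format != 1) {
    stop("unsupported WAV encoding (only integer PCM supported)",
         call. = FALSE)
  }
  if (fmt$n_channels < 4) {
    stop("recording must have at least 4 channels", call. = FALSE)
  }
  counts <- matrix(data_raw, ncol = fmt$n_channels, byrow = TRUE)

  sidecar_path <- paste0(path, ".json")
  meta <- if (file.exists(sidecar_path)) {
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  } else NULL

  if (!is.null(meta)) {
    upa_per_count <- meta$upa_per_count
    if (is.null(geometry)) {
      geometry <- array_geometry(
        hydrophone_depths = meta$hydrophone_depths,
        active_channels = meta$active_channels,
        reference_channel = meta$reference_channel)
    }
    if (is.null(environment)) {
      environment <- environment_profile(
        meta$environment$temperature, meta$environment$salinity,
        meta$environment$depth,
        sound_speed = meta$environment$sound_speed,
        ph = meta$environment$ph)
    }
  } else {
    upa_per_count <- full_scale_volts / 32767 /
      10^((sensitivity_db + gain_db) / 20)
    if (is.null(environment)) environment <- environment_profile(14, 33)
    if (is.null(geometry)) {
      geometry <- array_geometry(
        hydrophone_depths = seq(2, by = 0.75,
                                length.out = fmt$n_channels))
    }
  }
  if (geometry$n_channels != fmt$n_channels) {
    stop(sprintf(
      "channel-count mismatch: WAV has %d channels, geometry %d",
      fmt$n_channels, geometry$n_channels), call. = FALSE)
  }

  gt <- if (!is.null(meta$ground_truth)) {
    tibble::as_tibble(meta$ground_truth)
  } else NULL
  structure(
    list(samples = counts * upa_per_count, sample_rate = fmt$sample_rate,
         geometry = geometry, environment = environment,
         noise_spectral_level = meta$noise_spectral_level,
         upa_per_count = upa_per_count, ground_truth = gt,
         counts = counts),
    class = "array_recording"
  )
}
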