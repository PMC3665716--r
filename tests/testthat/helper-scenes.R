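# shared fixtures: canonical environments, array, and quick scene builders

bc_env <- function() environment_profile(9.2, 33.9)
dk_env <- function() environment_profile(15, 20)

std_geometry <- function() array_geometry()

# single-source scene with the array's default geometry; defaults emulate a
# Dall's porpoise at 30 m aiming at hydrophone 3
quick_scene <- function(range_m = 30, depth_m = 4.25, aim_at = 3L,
                        fc_khz = 137, duration_us = 104, sl_pp_db = 190,
                        aperture_cm = 10, ici_ms = rep(60, 4),
                        noise_db = 40, seed = 1, quantize = TRUE,
                        env = bc_env()) {
  src <- click_source_spec(c(range_m, 0, depth_m), aim_at = aim_at,
                           fc_khz = fc_khz, duration_10db_us = duration_us,
                           sl_pp_db = sl_pp_db, aperture_cm = aperture_cm,
                           ici_ms = ici_ms)
  scene_config(std_geometry(), env, src, noise_spectral_level = noise_db,
               seed = seed, quantize = quantize)
}

# exact TDOAs for a source position against the standard geometry
true_tdoas <- function(position, geometry = std_geometry(),
                       c_mps = as.numeric(sound_speed_mps(bc_env()))) {
  d <- sqrt(colSums((t(geometry$positions) - position)^2))
  ref <- geometry$reference_channel
  tibble::tibble(channel = geometry$active_channels,
                 tdoa_s = (d[geometry$active_channels] - d[ref]) / c_mps,
                 max_corr = 1, reliable = TRUE)
}
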