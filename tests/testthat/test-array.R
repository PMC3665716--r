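test_that("all clicks of a high-SNR scene are detected on all channels", {
  rec <- render_array_recording(quick_scene(ici_ms = rep(60, 9), seed = 2))
  scans <- detect_and_segment(rec)
  clicks <- dplyr::bind_rows(lapply(scans, `[[`, "clicks"))
  expect_equal(nrow(clicks), 10)
  expect_true(all(clicks$n_channels == 6))
  # determinism
  scans2 <- detect_and_segment(rec)
  expect_identical(dplyr::bind_rows(lapply(scans2, `[[`, "clicks"))$time_s,
                   clicks$time_s)
})

test_that("a source on a symmetry plane gives zero TDOA for the mirrored
           pair", {
  # source depth 4.25 m is equidistant from hydrophones 1 (z=2) and 6
  # (z=6.5)
  rec <- render_array_recording(quick_scene(seed = 42))
  scan <- detect_and_segment(rec)[[1]]
  td <- estimate_tdoas(scan$snippets[[2]],
                       rec$geometry$reference_channel)
  dt <- 1 / rec$sample_rate
  expect_lt(abs(td$tdoa_s[td$channel == 6]), dt)
})

test_that("an injected 17-sample shift is recovered to sub-sample
           precision", {
  w <- generate_nbhf_waveform(137, 104)
  n <- length(w$samples)
  shifted <- c(numeric(17), w$samples)[1:n]
  snips <- list(`1` = click_waveform(w$samples, 5e5, 1, 0),
                `2` = click_waveform(shifted, 5e5, 2, 0),
                `3` = click_waveform(w$samples, 5e5, 3, 0),
                `4` = click_waveform(w$samples, 5e5, 4, 0))
  td <- estimate_tdoas(snips, 1)
  expect_equal(td$tdoa_s[td$channel == 2] * 1e6, 34, tolerance = 0.5 / 34)
  expect_equal(td$tdoa_s[td$channel == 1], 0)
})

test_that("measured TDOAs match the scene geometry within one sample", {
  rec <- render_array_recording(quick_scene(noise_db = -Inf, seed = 3,
                                            quantize = FALSE))
  scan <- detect_and_segment(rec)[[1]]
  td <- estimate_tdoas(scan$snippets[[1]], 1)
  gt <- rec$ground_truth
  g <- gt[gt$click_id == 1, ]
  truth <- g$arrival_time_s - g$arrival_time_s[g$channel == 1]
  dt <- 1 / rec$sample_rate
  for (ch in 1:6) {
    expect_lt(abs(td$tdoa_s[td$channel == ch] - truth[g$channel == ch]), dt)
  }
})

test_that("noiseless localization recovers range within 2% inside 65 m", {
  cs <- as.numeric(sound_speed_mps(bc_env()))
  for (r in c(10, 30, 60)) {
    pos <- c(r, 0, 4.6)
    loc <- localize(true_tdoas(pos), std_geometry(), cs)
    r_true <- sqrt(sum((std_geometry()$positions[1, ] - pos)^2))
    expect_lt(abs(loc$range_to_reference - r_true) / r_true, 0.02)
    expect_lt(abs(loc$position[3] - 4.6), 0.5)
  }
})

test_that("all-zero TDOAs on a symmetric array are flagged degenerate", {
  cs <- as.numeric(sound_speed_mps(bc_env()))
  td <- tibble::tibble(channel = 1:6, tdoa_s = 0, max_corr = 1,
                       reliable = TRUE)
  loc <- localize(td, std_geometry(), cs)
  expect_true(loc$degenerate)
})

test_that("localization demands at least four reliable channels", {
  cs <- as.numeric(sound_speed_mps(bc_env()))
  td <- true_tdoas(c(20, 0, 4))[1:3, ]
  expect_error(localize(td, std_geometry(), cs), "fewer than 4")
})

test_that("TL rms error grows with TDOA jitter", {
  cs <- as.numeric(sound_speed_mps(bc_env()))
  td0 <- true_tdoas(c(20, 0, 4.25))
  mean_err <- vapply(c(0.5, 2, 8), function(j_us) {
    errs <- vapply(1:6, function(s) {
      set.seed(1000 * j_us + s)
      td <- td0
      td$tdoa_s <- td$tdoa_s + stats::rnorm(6, sd = j_us * 1e-6)
      localize(td, std_geometry(), cs)$tl_rms_error_db
    }, 0)
    mean(errs)
  }, 0)
  expect_true(all(diff(mean_err) > 0))
})

test_that("received levels on the array obey the propagation law", {
  rec <- render_array_recording(quick_scene(range_m = 20, sl_pp_db = 190,
                                            seed = 8))
  scan <- detect_and_segment(rec)[[1]]
  gt <- rec$ground_truth
  g <- gt[gt$click_id == 1 & gt$channel == 3, ]
  w <- scan$snippets[[1]][["3"]]
  rl <- compute_envelope_metrics(w)$rl_pp_db
  tl <- transmission_loss(g$range_m, absorption_coefficient(137, bc_env()))
  expect_lt(abs(rl - (190 - tl)), 1)
})

test_that("the scan maximum on a middle hydrophone is the only accepted
           click", {
  rec <- render_array_recording(quick_scene(seed = 4))
  scan <- detect_and_segment(rec)[[1]]
  dec <- select_on_axis(scan, rec)
  expect_equal(sum(dec$accepted), 1)
  expect_true(all(dec$crit_i))
  expect_true(dec$peak_channel[dec$accepted] %in% 2:5)
  # ground truth marks channel 3 as the on-axis channel
  expect_equal(dec$peak_channel[dec$accepted],
               rec$ground_truth$onaxis_channel[1])
})

test_that("a click aimed at the top hydrophone fails the middle-channel
           criterion", {
  rec <- render_array_recording(quick_scene(depth_m = 1.0, aim_at = 1L,
                                            seed = 5))
  scan <- detect_and_segment(rec)[[1]]
  dec <- select_on_axis(scan, rec)
  expect_true(all(dec$peak_channel == 1))
  expect_false(any(dec$crit_iv))
  expect_equal(sum(dec$accepted), 0)
})

test_that("a trailing surface echo stronger than the direct path fails
           criterion v", {
  sc <- quick_scene(seed = 6)
  rec <- render_array_recording(sc, surface_echo = list(delay_ms = 5,
                                                        level_db = 2))
  scan <- detect_and_segment(rec)[[1]]
  dec <- select_on_axis(scan, rec)
  expect_equal(sum(dec$accepted), 0)
  # every source click trips the echo criterion (its echo is 2 dB louder);
  # the detected echoes themselves have clean trailing windows
  direct <- dec$rl_pp_db < max(dec$rl_pp_db) - 1
  expect_true(any(direct))
  expect_false(any(dec$crit_v[direct]))
})

test_that("buzz clicks are excluded before on-axis selection", {
  rec <- render_array_recording(quick_scene(ici_ms = c(60, 5, 5, 60),
                                            seed = 9))
  scan <- detect_and_segment(rec)[[1]]
  dec <- select_on_axis(scan, rec)
  expect_equal(sum(dec$is_buzz), 2)
  expect_true(all(dec$reject_reason[dec$is_buzz] == "buzz"))
  expect_false(any(dec$accepted & dec$is_buzz))
})

test_that("five-channel mode relaxes the channel-count criterion", {
  geom5 <- array_geometry(active_channels = c(1, 2, 4, 5, 6),
                          reference_channel = 1)
  src <- click_source_spec(c(30, 0, 4.25), aim_at = 4L, ici_ms = rep(60, 3))
  sc <- scene_config(geom5, bc_env(), src, noise_spectral_level = 40,
                     seed = 10)
  rec <- render_array_recording(sc)
  scan <- detect_and_segment(rec)[[1]]
  dec6 <- select_on_axis(scan, rec, mode = "six_channel")
  dec5 <- select_on_axis(scan, rec, mode = "five_channel")
  expect_false(any(dec6$crit_i))   # only five channels exist
  expect_true(all(dec5$crit_i))
  expect_equal(sum(dec5$accepted), 1)
})

test_that("at most one click per scan is ever accepted", {
  for (seed in 1:3) {
    rec <- render_array_recording(quick_scene(ici_ms = rep(55, 6),
                                              seed = seed))
    for (scan in detect_and_segment(rec)) {
      dec <- select_on_axis(scan, rec)
      expect_lte(sum(dec$accepted), 1)
    }
  }
})
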