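test_that("WAV write/read round trip preserves counts exactly", {
  rec <- render_array_recording(quick_scene(ici_ms = rep(50, 2), seed = 5))
  tf <- withr::local_tempfile(fileext = ".wav")
  write_multichannel_wav(rec, tf)
  rec2 <- read_multichannel_wav(tf)
  expect_identical(rec2$counts,
                   matrix(as.integer(round(rec$samples /
                                             rec$upa_per_count)),
                          ncol = 6))
  expect_lt(max(abs(rec2$samples - rec$samples)) / max(abs(rec$samples)),
            1e-12)
  expect_equal(rec2$sample_rate, rec$sample_rate)
  expect_equal(nrow(rec2$ground_truth), nrow(rec$ground_truth))
})

test_that("channel-count mismatches against the geometry are refused", {
  rec <- render_array_recording(quick_scene(ici_ms = rep(50, 1), seed = 6))
  tf <- withr::local_tempfile(fileext = ".wav")
  write_multichannel_wav(rec, tf)
  geom5 <- array_geometry(hydrophone_depths = c(2, 3.5, 4.25, 5, 5.75))
  expect_error(read_multichannel_wav(tf, geometry = geom5),
               "channel-count mismatch")
})

test_that("the sensitivity chain maps full scale to 221 dB re 1 uPa", {
  rec <- render_array_recording(quick_scene(ici_ms = rep(50, 1), seed = 8))
  tf <- withr::local_tempfile(fileext = ".wav")
  write_multichannel_wav(rec, tf, sidecar = FALSE)
  rec2 <- read_multichannel_wav(tf, environment = bc_env())
  # peak was written at -6 dBFS, so the calibrated peak must sit ~6 dB
  # below the 221 dB full-scale level
  peak_db <- 20 * log10(max(abs(rec2$samples)))
  expect_lt(abs(peak_db - (221 - 20 * log10(2))), 0.1)
})

test_that("malformed WAV input fails loudly", {
  tf <- withr::local_tempfile(fileext = ".wav")
  writeBin(as.raw(rep(0, 64)), tf)
  expect_error(read_multichannel_wav(tf), "RIFF")
})

test_that("the pipeline is deterministic and honours a degenerate gate", {
  rec <- render_array_recording(quick_scene(seed = 15))
  r1 <- run_pipeline(rec, verbose = FALSE)
  r2 <- run_pipeline(rec, verbose = FALSE)
  expect_identical(r1$clicks, r2$clicks)
  expect_identical(r1$localizations, r2$localizations)
  # a 0 dB TL-error gate accepts nothing but completes cleanly
  r0 <- run_pipeline(rec, config = list(max_tl_error_db = 0),
                     verbose = FALSE)
  expect_equal(nrow(r0$clicks), 0)
  expect_equal(r0$manifest$n_gated, 0)
})

test_that("pipeline configuration can come from YAML", {
  rec <- render_array_recording(quick_scene(seed = 16))
  tf <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("threshold_db: 20", "max_range_m: 65",
               "centroid_method: median"), tf)
  res <- run_pipeline(rec, config = tf, verbose = FALSE)
  expect_equal(res$manifest$max_range_m, 65)
  expect_equal(nrow(res$clicks), 1)
})

test_that("pipeline output from a WAV file matches the in-memory path", {
  rec <- render_array_recording(quick_scene(seed = 17))
  tf <- withr::local_tempfile(fileext = ".wav")
  write_multichannel_wav(rec, tf)
  r_mem <- run_pipeline(rec, verbose = FALSE)
  r_wav <- run_pipeline(tf, verbose = FALSE)
  expect_equal(r_wav$clicks$f_centroid_khz, r_mem$clicks$f_centroid_khz,
               tolerance = 1e-9)
  expect_equal(r_wav$clicks$sl_pp_db, r_mem$clicks$sl_pp_db,
               tolerance = 1e-9)
})

test_that("tidiers and autoplots return well-formed objects", {
  set.seed(3)
  m <- monte_carlo_discrimination(stats::rnorm(300, 137, 3),
                                  stats::rnorm(300, 141, 2), 139,
                                  seed = 2)
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_true("criterion_khz" %in% names(td))
  expect_s3_class(autoplot(m), "ggplot")
  expect_s3_class(autoplot(noise_model()), "ggplot")
  roc <- roc_criterion(stats::rnorm(1000, 137, 3),
                       stats::rnorm(1000, 141, 2))
  expect_s3_class(tidy(roc), "tbl_df")
})
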