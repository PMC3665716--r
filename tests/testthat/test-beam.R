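test_that("off-axis angles reduce to plane geometry", {
  geom <- std_geometry()
  # source 10 m broadside of hydrophone 3; adjacent hydrophone 0.75 m away
  ang <- compute_offaxis_angles(c(10, 0, 4.25), geom, onaxis_channel = 3)
  expect_equal(ang$angle_deg[ang$channel == 3], 0)
  expect_equal(ang$angle_deg[ang$channel == 4],
               atan(0.75 / 10) * 180 / pi, tolerance = 1e-9)
})

test_that("scene off-axis angles match the ground-truth geometry", {
  rec <- render_array_recording(quick_scene(range_m = 12, seed = 13))
  gt <- rec$ground_truth[rec$ground_truth$click_id == 1, ]
  ang <- compute_offaxis_angles(c(gt$pos_x[1], gt$pos_y[1], gt$pos_z[1]),
                                rec$geometry,
                                onaxis_channel = gt$onaxis_channel[1])
  for (ch in 1:6) {
    expect_lt(abs(ang$angle_deg[ang$channel == ch] -
                    gt$angle_deg[gt$channel == ch]), 0.1)
  }
})

test_that("composite beam samples fall on the piston curve", {
  rec <- render_array_recording(quick_scene(range_m = 8, noise_db = -Inf,
                                            quantize = FALSE, seed = 14))
  res <- run_pipeline(rec, verbose = FALSE)
  cs <- as.numeric(sound_speed_mps(bc_env()))
  ka <- 2 * pi * 137e3 / cs * 0.05
  model <- 20 * log10(pmax(
    abs(2 * besselJ(pmax(ka * sin(res$beam$angle_deg * pi / 180), 1e-9), 1) /
          pmax(ka * sin(res$beam$angle_deg * pi / 180), 1e-9)), 1e-12))
  expect_lt(max(abs(res$beam$relative_level_db - model)), 0.5)
  # the on-axis sample of every click is exactly 0 dB
  onax <- res$beam$relative_level_db[res$beam$angle_deg == 0]
  expect_true(all(onax == 0))
})

test_that("clicks beyond the 20 m gate are excluded from the beam", {
  loc25 <- c(25, 0, 4.25)
  clicks <- list(list(loc = loc25, onaxis_channel = 3,
                      rl_by_channel = rep(150, 6)))
  expect_warning(
    beam <- build_composite_beam(clicks, std_geometry(), 0.04),
    "no accepted clicks")
  expect_equal(nrow(beam), 0)
})

test_that("the piston fit recovers a known 10 cm aperture", {
  rec <- render_array_recording(quick_scene(range_m = 8, seed = 7))
  res <- run_pipeline(rec, verbose = FALSE)
  expect_false(is.null(res$piston))
  expect_lt(abs(res$piston$aperture_cm - 10) / 10, 0.05)
  # porpoise-scale beams carry a directivity index in the mid-20s dB
  expect_true(dplyr::between(res$piston$directivity_index_db, 22, 29))
})

test_that("fitted DI matches brute-force quadrature of the same beam", {
  for (ka in c(10, 28.97, 40)) {
    th <- seq(0, pi, length.out = 100001)
    x <- pmax(ka * sin(th), 1e-12)
    b2 <- (2 * besselJ(x, 1) / x)^2
    b2[c(1, length(b2))] <- 1
    di_grid <- 10 * log10(2 / (sum(b2 * sin(th)) * pi / (length(th) - 1)))
    expect_lt(abs(piston_directivity_index(ka) - di_grid), 0.1)
  }
})

test_that("directivity grows with aperture at fixed frequency", {
  di <- vapply(c(5, 10, 20, 40), piston_directivity_index, 0)
  expect_true(all(diff(di) > 0))
})

test_that("the fit is invariant to a uniform dB offset of all samples", {
  rec <- render_array_recording(quick_scene(range_m = 8, seed = 7))
  res <- run_pipeline(rec, verbose = FALSE)
  shifted <- res$beam
  shifted$relative_level_db <- shifted$relative_level_db + 7
  cs <- as.numeric(sound_speed_mps(bc_env()))
  f1 <- fit_piston_beam(res$beam, 137, cs)
  f2 <- fit_piston_beam(shifted, 137, cs)
  expect_equal(f1$aperture_cm, f2$aperture_cm, tolerance = 1e-4)
  expect_equal(f1$directivity_index_db, f2$directivity_index_db,
               tolerance = 1e-4)
  expect_equal(f2$offset_db - f1$offset_db, 7, tolerance = 1e-4)
})

test_that("underdetermined beam samples are rejected", {
  few <- tibble::tibble(angle_deg = c(0, 5, 5, 0),
                        relative_level_db = c(0, -9, -9, 0))
  expect_error(fit_piston_beam(few, 137, 1486), ">= 5 samples")
})
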