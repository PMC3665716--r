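test_that("the masking-noise bandwidth term is 10log10 of the ratio", {
  nm <- noise_model()
  expect_equal(noise_level(130, 45, nm) - noise_level(130, 15, nm),
               10 * log10(3), tolerance = 1e-12)
  expect_equal(noise_level(130, 15, nm) - noise_level(130, 15, nm), 0)
})

test_that("the noise level equals band integration of a flat spectrum", {
  # oracle: for a spectrally flat noise floor, total noise in a band is the
  # spectral level plus 10log10(bandwidth in Hz)
  flat <- noise_model(table = data.frame(freq_khz = c(1, 250),
                                         spectral_db = c(30, 30)))
  bw_khz <- 15
  f_hz <- seq(100e3, 100e3 + bw_khz * 1e3, by = 10)
  integ <- 10 * log10(sum(10^(30 / 10) * rep(10, length(f_hz) - 1)))
  expect_lt(abs(noise_level(100, bw_khz, flat) - integ), 0.1)
})

test_that("the default noise floor has its minimum in the NBHF window", {
  f <- seq(20, 250, by = 0.5)
  lvl <- noise_spectral_level(f, noise_model())
  f_min <- f[which.min(lvl)]
  expect_true(dplyr::between(f_min, 90, 160))
  expect_error(noise_spectral_level(0.5, noise_model()), "support")
})

test_that("the committed noise fixture reproduces the parametric model", {
  fixture <- utils::read.csv(system.file(
    "extdata", "noise_deep_water_ss3_synthetic.csv",
    package = "nbhfclick"))
  expect_equal(fixture$spectral_db,
               noise_spectral_level(fixture$freq_khz, noise_model()),
               tolerance = 1e-3)
  nm_tab <- noise_model(table = fixture)
  expect_lt(abs(noise_spectral_level(130, nm_tab) -
                  noise_spectral_level(130, noise_model())), 0.2)
})

test_that("a scenario compared with itself sits exactly at 0 dB", {
  ref <- sonar_scenario(130, 15)
  cv <- delta_enr_curve(ref, ref)
  expect_true(all(cv$delta_enr_db == 0))
  expect_true(is.na(crossover_ranges(cv)$crossover_range_m))
})

test_that("tripling the bandwidth costs a constant 4.77 dB at every
           range", {
  ref <- sonar_scenario(130, 15)
  cv <- delta_enr_curve(sonar_scenario(130, 45), ref)
  expect_equal(unique(cv$delta_enr_db), -10 * log10(3), tolerance = 1e-12)
  expect_true(is.na(crossover_ranges(cv)$crossover_range_m))
})

test_that("a 200 kHz click never beats the NBHF reference", {
  ref <- sonar_scenario(130, 15)
  cv <- delta_enr_curve(sonar_scenario(200, 15), ref,
                        ranges_m = seq(1, 1000, by = 1))
  expect_true(all(cv$delta_enr_db < 0))
})

test_that("the curve decomposes exactly into its three closed-form terms", {
  ref <- sonar_scenario(130, 15)
  env <- environment_profile(14, 33)
  nm <- noise_model()
  for (fc in c(32.5, 65, 200)) for (bw in c(15, 45)) {
    cv <- delta_enr_curve(sonar_scenario(fc, bw), ref,
                          ranges_m = c(1, 50, 500), nm = nm)
    d_alpha <- absorption_coefficient(fc, env) -
      absorption_coefficient(130, env)
    d_noise <- noise_spectral_level(fc, nm) - noise_spectral_level(130, nm)
    d_bw <- 10 * log10(bw / 15)
    closed <- -2 * c(1, 50, 500) * d_alpha - d_noise - d_bw
    expect_equal(cv$delta_enr_db, closed, tolerance = 1e-9)
    trm <- attr(cv, "terms")
    expect_equal(trm$absorption_db_per_m, d_alpha, tolerance = 1e-12)
    expect_equal(trm$noise_window_db, d_noise, tolerance = 1e-12)
    expect_equal(trm$bandwidth_db, d_bw, tolerance = 1e-12)
  }
})

test_that("low-frequency broadband clicks only win beyond 100 m", {
  ref <- sonar_scenario(130, 15)
  for (fc in c(32.5, 65)) {
    cv <- delta_enr_curve(sonar_scenario(fc, 45), ref)
    x <- crossover_ranges(cv)$crossover_range_m
    expect_false(is.na(x))
    expect_gt(x, 100)
    expect_lt(x, 1000)
    # worse than the reference before the crossover, better after
    expect_true(all(cv$delta_enr_db[cv$range_m < x - 1] < 0))
    expect_true(all(cv$delta_enr_db[cv$range_m > x + 1] > 0))
  }
})

test_that("mismatched fixed terms are refused", {
  ref <- sonar_scenario(130, 15)
  other <- sonar_scenario(65, 45, ts = 10)
  expect_error(delta_enr_curve(other, ref), "fixed terms")
})

test_that("peak-pressure/energy equivalence follows the duration ratio", {
  expect_equal(efd_pp_equivalence(100, 200, 25), 200 + 10 * log10(4),
               tolerance = 1e-12)
  expect_equal(round(efd_pp_equivalence(100, 200, 25)), 206)
  expect_equal(efd_pp_equivalence(80, 190, 80), 190)
  # four times the duration buys 6.02 dB of energy at fixed peak pressure
  expect_equal(efd_pp_equivalence(400, 200, 100) - 200, 10 * log10(4),
               tolerance = 1e-12)
  expect_error(efd_pp_equivalence(-1, 200, 25), "positive")
})
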