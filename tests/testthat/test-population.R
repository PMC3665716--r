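test_that("a flat audiogram is the identity filter", {
  w <- generate_nbhf_waveform(137, 104)
  flat <- audiogram(c(10, 50, 100, 200), rep(55, 4), name = "flat")
  wf <- audiogram_filter(w, flat)
  expect_lt(max(abs(wf$samples - w$samples)), 1e-10)
})

test_that("steep high-frequency hearing loss pulls the centroid down", {
  w <- generate_nbhf_waveform(141, 88)
  wf <- audiogram_filter(w, default_audiogram())
  fc0 <- compute_spectral_metrics(w)$f_centroid_khz
  fc1 <- compute_spectral_metrics(wf)$f_centroid_khz
  expect_lt(fc1, fc0)
  # oracle: direct spectral multiplication predicts the same centroid
  n <- length(w$samples)
  f <- abs(nbhfclick:::fft_bin_freqs(n, w$sample_rate)) / 1e3
  aud <- default_audiogram()
  gain_db <- -(nbhfclick:::audiogram_threshold(aud, f) -
                 min(aud$threshold_db))
  oracle <- Re(stats::fft(stats::fft(w$samples) * 10^(gain_db / 20),
                          inverse = TRUE)) / n
  expect_lt(max(abs(oracle - wf$samples)), 1e-9)
})

test_that("filtering twice equals the squared filter once", {
  w <- generate_nbhf_waveform(137, 104)
  aud <- default_audiogram()
  twice <- audiogram_filter(audiogram_filter(w, aud), aud)
  once_sq <- audiogram_filter(w, aud, squared = TRUE)
  expect_lt(max(abs(twice$samples - once_sq$samples)), 1e-6)
})

test_that("clicks outside the audiogram support are rejected", {
  aud <- default_audiogram()
  lowclick <- click_waveform(
    generate_nbhf_waveform(12, 300, sample_rate = 1e5)$samples, 1e5)
  expect_error(audiogram_filter(lowclick, aud), "outside audiogram")
})

test_that("the ROC criterion separates the two species at 139 kHz", {
  set.seed(101)
  a <- stats::rnorm(2e4, 137, 3)
  b <- stats::rnorm(2e4, 141, 2)
  roc <- roc_criterion(a, b)
  expect_equal(roc$criterion_int_khz, 139)
  expect_true(dplyr::between(roc$criterion_khz, 138, 140))
  # swapping the class labels keeps the threshold, inverts the rule
  roc_sw <- roc_criterion(b, a)
  expect_equal(roc_sw$criterion_khz, roc$criterion_khz, tolerance = 0.2)
  expect_equal(roc_sw$direction, "a_above")
})

test_that("identical distributions give chance accuracy; constants error", {
  set.seed(5)
  x <- stats::rnorm(5e3, 139, 2)
  roc <- roc_criterion(x, x)
  expect_lt(abs(roc$accuracy - 0.5), 0.02)
  expect_error(roc_criterion(rep(139, 10), rep(139, 10)), "degenerate")
})

test_that("Monte Carlo discrimination is seed-reproducible and improves
           with set size", {
  set.seed(77)
  a <- stats::rnorm(600, 137, 3)
  b <- stats::rnorm(600, 141, 2)
  m1 <- monte_carlo_discrimination(a, b, 139, seed = 5)
  m2 <- monte_carlo_discrimination(a, b, 139, seed = 5)
  expect_identical(m1$percent_correct, m2$percent_correct)
  expect_gte(m1$percent_correct[m1$set_size == 32],
             m1$percent_correct[m1$set_size == 1])
  expect_true(all(m1$percent_correct >= 0 & m1$percent_correct <= 100))
  expect_true(all(m1$sem >= 0))
})

test_that("identical populations classify at chance at every set size", {
  set.seed(42)
  x <- stats::rnorm(600, 139, 2.5)
  m <- monte_carlo_discrimination(x, x, 139, seed = 8)
  expect_true(all(abs(m$percent_correct - 50) < 6))
})

test_that("sets larger than the dataset fall back to replacement with a
           warning", {
  expect_warning(
    m <- monte_carlo_discrimination(stats::rnorm(10, 137, 3),
                                    stats::rnorm(10, 141, 2),
                                    139, set_sizes = c(16), seed = 4),
    "replacement")
  expect_true(attr(m, "replacement_used"))
})

test_that("species ordering of centroid frequencies survives audiogram
           filtering", {
  aud <- default_audiogram()
  da <- simulate_click_dataset("bc_dalls", 12, seed = 31)
  db <- simulate_click_dataset("bc_harbour", 12, seed = 32)
  da_f <- simulate_click_dataset("bc_dalls", 12, seed = 31,
                                 audiogram = aud)
  db_f <- simulate_click_dataset("bc_harbour", 12, seed = 32,
                                 audiogram = aud)
  expect_gt(mean(db$f_centroid_khz), mean(da$f_centroid_khz))
  expect_gt(mean(db_f$f_centroid_khz), mean(da_f$f_centroid_khz))
  # filtering with poorer sensitivity above 100 kHz lowers both species
  expect_lt(mean(da_f$f_centroid_khz), mean(da$f_centroid_khz))
  expect_lt(mean(db_f$f_centroid_khz), mean(db$f_centroid_khz))
})

test_that("the simulated click datasets mix on- and off-axis clicks 1:5", {
  d <- simulate_click_dataset("bc_dalls", 6, seed = 21)
  expect_equal(nrow(d), 36)
  expect_equal(sum(d$is_onaxis), 6)
  expect_equal(sum(!d$is_onaxis), 30)
})

test_that("source-level diagnostics recover trends and ICI bands", {
  set.seed(9)
  clicks <- tibble::tibble(
    population = rep(c("a", "b"), each = 60),
    range_m = stats::runif(120, 5, 65),
    ici_ms = stats::runif(120, 0, 200))
  clicks$sl_pp_db <- ifelse(clicks$population == "a",
                            170 + 0.2 * clicks$range_m,
                            185 + stats::rnorm(120, 0, 3))
  d <- sl_trend_diagnostics(clicks)
  a_reg <- d$regression[d$regression$group == "a", ]
  expect_equal(a_reg$slope, 0.2, tolerance = 1e-9)
  expect_equal(a_reg$r_squared, 1, tolerance = 1e-9)
  b_reg <- d$regression[d$regression$group == "b", ]
  expect_lt(abs(b_reg$slope), 0.15)
  expect_lt(b_reg$r_squared, 0.2)
  # band assignment: an ICI of 45 ms lands in the 40-60 band
  one <- tibble::tibble(population = "a", sl_pp_db = 180, range_m = 10,
                        ici_ms = 45)
  band <- sl_trend_diagnostics(one)$ici_bands
  expect_equal(as.character(band$band), "40-60 ms")
  expect_true(is.na(band$sd_sl_db))
})
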