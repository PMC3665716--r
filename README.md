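# nbhfclick

Analysis of narrow-band high-frequency (NBHF) echolocation clicks recorded
on vertical hydrophone arrays, for bioacousticians studying porpoises and
other NBHF species (*Phocoena*, *Phocoenoides*, *Cephalorhynchus*, *Kogia*).
The package covers the full workflow from a six-channel recording to
species-level inference: on-axis click selection, source parameterization,
acoustic localization, apparent source levels, transmission beam patterns,
centroid-frequency species discrimination, and a sonar-equation model of
what the NBHF click design buys its user. A synthetic-scene simulator with
known ground truth makes every stage testable without field recordings.

## The science in brief

**Click parameterization.** An on-axis click is described by eleven source
parameters: the −10 dB envelope duration (Hilbert envelope crossings), peak
and centroid frequency, −3 dB / −10 dB / rms bandwidths, the quality
factors Q(rms) = F(c)/BW(rms) and Q(−3dB) = F(peak)/BW(−3dB), and three
received levels (peak–peak; rms and energy flux density over the −10 dB
window). The centroid frequency is the frequency dividing the power
spectrum into two halves of equal energy, computed on a 512-point
rectangular-window spectrum interpolated ×10.

**Localization and source level.** Arrival-time differences across the
over-determined six-element array are fit by Levenberg–Marquardt least
squares; leave-one-hydrophone-out sub-solutions give an error estimate on
the transmission loss. Apparent source level back-calculates

    SL = RL + 20 log10(r) + alpha * r

with `alpha` the seawater absorption coefficient (Fisher & Simmons-style
boric-acid + MgSO4 + viscous relaxation terms) at the clicks' centroid
frequency. Only clicks localized within 65 m with a TL rms error below
3 dB are used.

**Beam pattern.** For each accepted click the five off-axis hydrophones
sample the transmission beam; pooled samples from clicks within 20 m are
fit by a circular-piston model `20 log10 |2 J1(ka sin θ)/(ka sin θ)|`,
giving an equivalent aperture and, by integration over the rotationally
symmetric beam, a directivity index.

**Species discrimination.** Clicks are filtered through an inverted
audiogram (reception emulation), and sets of N clicks (one on-axis : five
off-axis) are classified by whether their mean centroid frequency falls
below (Dall's porpoise, 137 ± 3 kHz) or above (BC harbour porpoise,
141 ± 2 kHz) a ROC-optimal criterion of 139 kHz.

**Detection-range model.** The active sonar equation
`ENR = SL − 2TL + TS + DI − NL`, with `NL = N0(Fc) + 10 log10(BW_rms)`,
compares click designs of centroid frequency {32.5, 65, 130, 200} kHz and
rms bandwidth {15, 45} kHz against the 130 kHz / 15 kHz NBHF reference at
equal source energy flux density (ΔENR curves versus target range).

## Worked example

Simulate a porpoise clicking at a six-element vertical array and run the
pipeline end to end:

```r
library(nbhfclick)

env  <- environment_profile(9.2, 33.9)        # British Columbia site
geom <- array_geometry()                      # 6 elements, 0.75 m spacing,
                                              # 1.5 m top gap
src  <- click_source_spec(c(30, 0, 4.25), aim_at = 3L, fc_khz = 137,
                          duration_10db_us = 104, sl_pp_db = 190,
                          aperture_cm = 10, ici_ms = rep(60, 4))
rec  <- render_array_recording(
  scene_config(geom, env, src, noise_spectral_level = 40, seed = 42))
res  <- run_pipeline(rec)
#> detected 5 clicks in 1 scans
#> accepted 1 on-axis clicks (1 localized within the 65 m / <3 dB gate)
#>   rejected 4: not scan maximum

res$clicks[, c("f_centroid_khz", "duration_10db_us", "sl_pp_db", "range_m")]
#> # A tibble: 1 × 4
#>   f_centroid_khz duration_10db_us sl_pp_db range_m
#> 1           137.             104.     190.    30.1
```

One click per scan survives the six on-axis criteria; its measured centroid
frequency (137 kHz), duration (104 µs) and back-calculated source level
(190 dB re 1 µPa pp) recover the simulated ground truth, at the localized
range of 30.1 m. A closer scene (within the 20 m beam gate) also yields the
beam fit:

```r
res8 <- run_pipeline(render_array_recording(
  scene_config(geom, env,
               click_source_spec(c(8, 0, 4.25), ici_ms = rep(60, 3)),
               noise_spectral_level = 40, seed = 7)))
#> piston fit: aperture 9.9 cm, DI 26.2 dB
```

The 10 cm simulated aperture is recovered, with a directivity index of
26 dB — the mid-20s DI that porpoise-sized biosonars converge on. The
species-discrimination and detection-range components run from tables, not
recordings:

```r
roc <- roc_criterion(rnorm(2e4, 137, 3), rnorm(2e4, 141, 2))
roc$criterion_int_khz
#> [1] 139

curves <- dplyr::bind_rows(
  delta_enr_curve(sonar_scenario(32.5, 45), sonar_scenario(130, 15)),
  delta_enr_curve(sonar_scenario(65, 45),  sonar_scenario(130, 15)))
crossover_ranges(curves)
#> # A tibble: 2 × 2
#>   scenario          crossover_range_m
#> 1 32.5 kHz / 45 kHz              167.
#> 2 65 kHz / 45 kHz                148.
```

Broadband lower-frequency clicks of equal source energy only out-detect the
NBHF design beyond ~150 m; at shorter ranges the narrow band and the
low-noise window around 130 kHz win.

## Package layout

| area | functions |
|---|---|
| synthetic scenes | `generate_nbhf_waveform`, `apply_piston_offaxis`, `propagate_click`, `render_array_recording`, `sample_population_parameters` |
| click metrics | `click_parameters`, `compute_envelope_metrics`, `compute_spectral_metrics` |
| array processing | `detect_and_segment`, `estimate_tdoas`, `localize`, `select_on_axis` |
| environment | `environment_profile`, `sound_speed_mps`, `absorption_coefficient`, `transmission_loss` |
| source level | `apparent_source_level` |
| beam pattern | `compute_offaxis_angles`, `build_composite_beam`, `fit_piston_beam`, `piston_directivity_index` |
| discrimination | `audiogram_filter`, `roc_criterion`, `monte_carlo_discrimination`, `simulate_click_dataset`, `sl_trend_diagnostics` |
| sonar model | `noise_model`, `noise_level`, `sonar_scenario`, `delta_enr_curve`, `crossover_ranges`, `efd_pp_equivalence` |
| I/O & pipeline | `read_multichannel_wav`, `write_multichannel_wav`, `run_pipeline` |

Fitted objects support `tidy()`, `glance()` and `autoplot()`; see the
methods vignette (`vignettes/nbhf-click-analysis.Rmd`) for the full model
description, parameter defaults, and known limitations.
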