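test_that("generate_semg is deterministic and band-checked", {
  a <- generate_semg(1, 2000, c(20, 500), seed = 3)
  b <- generate_semg(1, 2000, c(20, 500), seed = 3)
  expect_identical(a$samples, b$samples)
  c2 <- generate_semg(1, 2000, c(20, 500), seed = 4)
  expect_false(identical(a$samples, c2$samples))
  expect_error(generate_semg(1, 2000, c(20, 1100)), "parameter error")
  expect_error(generate_semg(1, 2000, c(0, 500)), "parameter error")
  # RMS calibration
  expect_equal(rms(generate_semg(2, 2000, c(20, 500), amplitude = 0.25,
                                 seed = 9)$samples), 0.25, tolerance = 1e-9)
})

test_that("flat-band sEMG has its analytic median; lower bands give lower MDF", {
  est_mdf <- function(band, seed, dur = 2) {
    s <- generate_semg(dur, 2000, band, seed = seed)
    median_frequency(power_spectrum(s))
  }
  expect_lt(abs(est_mdf(c(20, 500), 1, dur = 10) - 260) / 260, 0.05)
  lower <- vapply(1:20, function(s) est_mdf(c(20, 400), s), numeric(1))
  upper <- vapply(1:20, function(s) est_mdf(c(20, 500), s), numeric(1))
  expect_true(all(lower < upper))
  expect_lt(abs(mean(lower) - 210), 10)
  expect_lt(abs(mean(upper) - 260), 10)
})

test_that("pink-shaped sEMG sits below the flat analytic median", {
  flat <- generate_semg(5, 2000, c(20, 500), seed = 2)
  pink <- generate_semg(5, 2000, c(20, 500), seed = 2, shape = "pink")
  mdf_flat <- median_frequency(power_spectrum(flat))
  mdf_pink <- median_frequency(power_spectrum(pink))
  expect_lt(mdf_pink, mdf_flat - 50)
})

test_that("pressure bursts hit their configured peaks and cadence", {
  clean <- generate_pressure_channel(10, 100, 1000, step_rate_hz = 1,
                                     noise_cv = 0, seed = 1)
  ev <- detect_steps(clean)
  expect_equal(nrow(ev), 10L)
  expect_true(all(abs(ev$peak_value - 1000) / 1000 <= 0.02))
  expect_true(all(clean$samples >= 0))

  noisy <- generate_pressure_channel(100, 100, 1000, step_rate_hz = 1,
                                     noise_cv = 0.1, seed = 2)
  evn <- detect_steps(noisy)
  cv <- sd(evn$peak_value) / mean(evn$peak_value)
  expect_gte(cv, 0.05)
  expect_lte(cv, 0.15)

  expect_error(generate_pressure_channel(10, 100, -5), "parameter error")
  expect_error(generate_pressure_channel(0.5, 100, 100, step_rate_hz = 1),
               "parameter error")
})

test_that("apply_fatigue rescales regions and shifts sEMG bands", {
  cfg <- synthetic_config()
  post <- apply_fatigue(cfg)
  # printed right-HA post mean reproduced within 0.1%
  expect_lt(abs(post$region_mean_peaks_gf[["prs_R_HA"]] - 595.1) / 595.1,
            0.001)
  # analytic medians move by the configured shifts
  med <- function(b) (b[1] + b[2]) / 2
  expect_equal(med(post$emg_band_pre$emg_L_GA) - med(cfg$emg_band_pre$emg_L_GA),
               -7.5)
  expect_equal(med(post$emg_band_pre$emg_R_GA) - med(cfg$emg_band_pre$emg_R_GA),
               -9.2)
  expect_equal(post$emg_band_pre$emg_L_RF, cfg$emg_band_pre$emg_L_RF)

  # identity operators leave the config unchanged
  null <- null_config(1)
  post_null <- apply_fatigue(null)
  expect_equal(post_null$region_mean_peaks_gf, null$region_mean_peaks_gf)
  expect_equal(post_null$emg_band_pre, null$emg_band_pre)
})

test_that("generate_cohort bookkeeping, determinism and zero-CV behaviour", {
  cfg <- small_config()
  coh <- generate_cohort(cfg)
  expect_length(coh, cfg$n_subjects * 2 * cfg$n_trials * 2)
  emg <- Filter(function(r) r$rate_hz == 2000, coh)
  prs <- Filter(function(r) r$rate_hz == 100, coh)
  expect_length(emg, cfg$n_subjects * 2 * cfg$n_trials)
  expect_true(all(vapply(emg, function(r) length(r$signals) == 4L,
                         logical(1))))
  expect_true(all(vapply(prs, function(r) length(r$signals) == 12L,
                         logical(1))))
  expect_setequal(unique(vapply(coh, function(r) r$condition, character(1))),
                  c("pre", "post"))

  coh2 <- generate_cohort(small_config())
  expect_identical(coh[[1]]$signals[[1]]$samples,
                   coh2[[1]]$signals[[1]]$samples)
  expect_identical(coh[[24]]$signals[[5]]$samples,
                   coh2[[24]]$signals[[5]]$samples)

  flat <- generate_cohort(small_config(between_subject_cv = 0),
                          modalities = "pressure")
  sp <- attr(flat, "subject_params")
  expect_true(all(vapply(sp, function(p) all(p$region_mult == 1),
                         logical(1))))
})

test_that("recovered percent change tracks the sign of (factor - 1)", {
  # small cohort, long trials: direction check per affected region
  cfg <- synthetic_config(n_subjects = 2, trial_duration_s = 10,
                          between_subject_cv = 0, seed = 77)
  coh <- generate_cohort(cfg, modalities = "pressure")
  res <- analyze_cohort(coh)$pressure
  pre <- res[res$condition == "pre", ]
  post <- res[res$condition == "post", ]
  for (ch in pressure_channels()) {
    fac <- cfg$fatigue_factors[[ch]]
    if (abs(fac - 1) < 0.05) next
    pc <- percent_change(mean(pre$mean_peak_gf[pre$channel == ch]),
                         mean(post$mean_peak_gf[post$channel == ch]))
    expect_identical(sign(pc), sign(fac - 1))
  }
})
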