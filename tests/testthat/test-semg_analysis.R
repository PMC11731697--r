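test_that("bandpass_fir passes the band and rejects DC and sub-band tones", {
  tone100 <- make_tone(100)
  out <- bandpass_fir(tone100)
  expect_equal(length(out), length(tone100))
  expect_equal(out$rate_hz, tone100$rate_hz)
  # passband: RMS within 12% of the analytic input RMS (1/sqrt(2))
  expect_lt(abs(rms_interior(out$samples) - 1 / sqrt(2)) / (1 / sqrt(2)),
            0.12)

  dc <- sampled_signal(rep(1, 4000), 2000, "dc")
  expect_lt(rms_interior(bandpass_fir(dc)$samples), 0.01)

  tone5 <- make_tone(5)
  expect_lt(rms_interior(bandpass_fir(tone5)$samples) / (1 / sqrt(2)), 0.01)
})

test_that("bandpass_fir validates its parameters", {
  s <- make_tone(100)
  expect_error(bandpass_fir(s, 20, 1000), "Nyquist")
  expect_error(bandpass_fir(s, 500, 20), "low_hz < high_hz")
  short <- sampled_signal(rnorm(300), 2000, "short")
  expect_error(bandpass_fir(short), "length error")
})

test_that("power_spectrum concentrates a tone and satisfies Parseval", {
  # bin-aligned tone (integer cycles): a single dominant bin
  aligned <- make_tone(150, duration_s = 2)
  spa <- power_spectrum(aligned, method = "periodogram")
  expect_equal(spa$freqs_hz[which.max(spa$power)], 150)
  expect_gte(max(spa$power) / sum(spa$power), 0.99)

  # 4096 samples put 150 Hz between bins; rectangular-window leakage
  # spreads power, but >= 95% of it stays within +/- 2 bins of the peak
  tone <- make_tone(150, duration_s = 4096 / 2000)
  sp <- power_spectrum(tone, method = "periodogram")
  peak_bin <- which.max(sp$power)
  expect_equal(sp$freqs_hz[peak_bin], 150, tolerance = 2 * sp$resolution_hz)
  near <- max(1, peak_bin - 2):min(length(sp$power), peak_bin + 2)
  expect_gte(sum(sp$power[near]) / sum(sp$power), 0.95)

  withr::with_seed(11, {
    noise <- sampled_signal(rnorm(4000), 2000, "white")
  })
  spw <- power_spectrum(noise)
  expect_true(all(spw$power > 0))
  expect_true(!is.unsorted(spw$freqs_hz, strictly = TRUE))

  # Parseval: summed power equals the time-domain mean square
  ms <- mean(noise$samples^2)
  expect_equal(sum(power_spectrum(noise, method = "periodogram")$power), ms,
               tolerance = 1e-10)
  expect_lt(abs(sum(spw$power) - ms) / ms, 1e-10)

  zero <- sampled_signal(rep(0, 1000), 2000, "zero")
  expect_error(power_spectrum(zero), "degenerate")
})

test_that("median_frequency follows the discrete equal-power convention", {
  one_bin <- structure(list(freqs_hz = c(50, 100, 200),
                            power = c(0, 5, 0)), class = "power_spectrum")
  expect_equal(median_frequency(one_bin), 100)

  # flat spectrum spanning 20-500 Hz at 1 Hz bins: midpoint bin
  f <- 20:500
  flat <- structure(list(freqs_hz = f, power = rep(1, length(f))),
                    class = "power_spectrum")
  expect_equal(median_frequency(flat), 260, tolerance = 1)

  two <- structure(list(freqs_hz = c(50, 150), power = c(3, 1)),
                   class = "power_spectrum")
  expect_equal(median_frequency(two), 50)

  expect_error(
    median_frequency(structure(list(freqs_hz = c(1, 2), power = c(0, 0)),
                               class = "power_spectrum")),
    "degenerate")
})

test_that("median_frequency split property and scale invariance hold", {
  withr::with_seed(99, {
    for (i in 1:100) {
      m <- sample(3:60, 1)
      f <- sort(runif(m, 1, 500))
      p <- runif(m)
      p[sample(m, sample(0:(m - 1), 1))] <- 0
      if (sum(p) == 0) p[1] <- 1
      sp <- structure(list(freqs_hz = f, power = p),
                      class = "power_spectrum")
      mdf <- median_frequency(sp)
      total <- sum(p)
      expect_lte(sum(p[f < mdf]), total / 2)
      expect_gte(sum(p[f <= mdf]), total / 2)
      # invariance under uniform power scaling
      sp$power <- p * runif(1, 0.01, 100)
      expect_identical(median_frequency(sp), mdf)
    }
  })
})

test_that("mdf_for_condition averages per-trial MDFs", {
  trial <- generate_semg(2, 2000, c(20, 300), seed = 5, label = "emg_L_GA")
  res <- mdf_for_condition(list(trial, trial, trial), "emg_L_GA", "pre")
  expect_equal(res$n_trials_averaged, 3L)
  expect_equal(res$mdf_hz, res$per_trial_mdf_hz[[1]])
  expect_equal(res$mdf_hz, mean(res$per_trial_mdf_hz))

  trials <- lapply(1:3, function(s) {
    generate_semg(10, 2000, c(20, 500), seed = s, label = "emg_L_GA")
  })
  res260 <- mdf_for_condition(trials, "emg_L_GA", "pre")
  expect_lt(abs(res260$mdf_hz - 260), 10)

  expect_error(mdf_for_condition(list(), "emg_L_GA", "pre"), "input error")
})

test_that("spectrum-averaging and rectified modes stay close to the default", {
  trials <- lapply(1:3, function(s) {
    generate_semg(5, 2000, c(20, 300), seed = 100 + s, label = "emg_L_GA")
  })
  default <- mdf_for_condition(trials, "emg_L_GA", "pre")
  spec_avg <- mdf_for_condition(trials, "emg_L_GA", "pre",
                                aggregate = "spectrum")
  expect_lt(abs(default$mdf_hz - spec_avg$mdf_hz), 10)
  rect <- mdf_for_condition(trials, "emg_L_GA", "pre", rectify = TRUE)
  expect_true(is.finite(rect$mdf_hz))
  expect_false(isTRUE(all.equal(rect$mdf_hz, default$mdf_hz)))
})

test_that("fatigue_shift reports the printed pre-to-post decreases", {
  mk <- function(mdf, cond) {
    structure(list(mdf_hz = mdf, muscle = "emg_L_GA", condition = cond,
                   n_trials_averaged = 3), class = "mdf_result")
  }
  expect_equal(fatigue_shift(mk(93.6, "pre"), mk(86.1, "post")), -7.5)
  expect_equal(fatigue_shift(mk(81.3, "pre"), mk(72.1, "post")), -9.2)
  expect_equal(fatigue_shift(mk(90, "pre"), mk(90, "post")), 0)
  other <- structure(list(mdf_hz = 80, muscle = "emg_R_GA"),
                     class = "mdf_result")
  expect_error(fatigue_shift(mk(90, "pre"), other), "different muscles")
})

test_that("downward band shifts strictly decrease the estimated MDF", {
  bands <- list(c(20, 500), c(20, 400), c(20, 300))
  mdfs <- vapply(seq_along(bands), function(i) {
    s <- generate_semg(5, 2000, bands[[i]], seed = 7, label = "emg")
    median_frequency(power_spectrum(bandpass_fir(s)))
  }, numeric(1))
  expect_true(all(diff(mdfs) < 0))
})
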