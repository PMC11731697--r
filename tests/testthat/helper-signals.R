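# Shared fixtures built in code.

make_tone <- function(freq_hz, rate_hz = 2000, duration_s = 2,
                      amplitude = 1, label = "tone") {
  t <- (seq_len(round(duration_s * rate_hz)) - 1) / rate_hz
  sampled_signal(amplitude * sin(2 * pi * freq_hz * t), rate_hz, label)
}

rms <- function(x) sqrt(mean(x^2))

# RMS with filter-length edge samples discarded (transients excluded)
rms_interior <- function(x, edge = 500) {
  n <- length(x)
  rms(x[(edge + 1):(n - edge)])
}

# Train of half-sine bursts with known amplitudes; used as the
# step-detection ground truth.
make_burst_train <- function(n_bursts, amplitude = 1000, burst_s = 0.3,
                             period_s = 1, rate_hz = 100, noise_sd = 0,
                             label = "prs") {
  n <- round((n_bursts * period_s) * rate_hz)
  x <- numeric(n)
  nb <- round(burst_s * rate_hz)
  if (nb %% 2 == 0) nb <- nb + 1L  # odd length: a sample at the exact apex
  shape <- sin(pi * (0:(nb - 1)) / (nb - 1))
  centers <- integer(n_bursts)
  for (k in seq_len(n_bursts)) {
    i0 <- round((k - 1) * period_s * rate_hz) + 1L
    idx <- i0:(i0 + nb - 1L)
    x[idx] <- amplitude * shape
    centers[k] <- i0 + which.max(shape) - 1L
  }
  if (noise_sd > 0) x <- pmax(0, x + stats::rnorm(n, 0, noise_sd))
  list(signal = sampled_signal(x, rate_hz, label), centers = centers,
       amplitude = amplitude)
}

# A small pre/post long table pair for the pairing machinery.
make_region_table <- function(values, channel = "prs_R_HA") {
  data.frame(subject_id = sprintf("S%02d", seq_along(values)),
             channel = channel, mean_peak_gf = values,
             stringsAsFactors = FALSE)
}

# Fast small config for bookkeeping-level tests.
small_config <- function(...) {
  synthetic_config(n_subjects = 2, trial_duration_s = 1.5, seed = 42, ...)
}

# Null (no-fatigue) config used by type-I simulations.
null_config <- function(seed, trial_duration_s = 5, n_subjects = 12) {
  base <- synthetic_config()
  synthetic_config(
    n_subjects = n_subjects,
    trial_duration_s = trial_duration_s,
    fatigue_factors = setNames(rep(1, length(base$fatigue_factors)),
                               names(base$fatigue_factors)),
    mdf_shift_hz = setNames(rep(0, length(base$mdf_shift_hz)),
                            names(base$mdf_shift_hz)),
    seed = seed)
}
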