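# Synthetic cohort generator. Emulates the wearable protocol's signals:
# band-limited Gaussian sEMG whose analytic spectral median is
# (low + high) / 2, and periodic half-sine gait pressure bursts per
# anatomical region. Fatigue is a downward shift of the sEMG band and a
# forefoot-to-hindfoot redistribution of burst amplitudes.

#' Synthetic protocol configuration
#'
#' Defaults instantiate the printed study conditions: 12 subjects, 3
#' trials per condition, sEMG at 2000 Hz and pressure at 100 Hz. sEMG
#' bands are chosen so the analytic median frequency equals the printed
#' prefatigue gastrocnemius MDFs (93.6 Hz left, 81.3 Hz right); fatigue
#' shifts them by the printed decreases (-7.5 / -9.2 Hz) while the rectus
#' femoris is unshifted. Prefatigue region mean peaks and fatigue factors
#' come from the printed pressure means and percent changes (hallux and
#' lesser-toe loading down ~1/3, medial heel up 7-11%, other regions
#' unchanged).
#'
#' @param n_subjects Number of subjects (default 12).
#' @param emg_rate_hz sEMG sampling rate (default 2000 Hz).
#' @param pressure_rate_hz Pressure sampling rate (default 100 Hz).
#' @param trial_duration_s Trial length in seconds (default 10).
#' @param n_trials Trials per condition (default 3).
#' @param emg_band_pre Named list of `c(low, high)` Hz per sEMG channel.
#' @param mdf_shift_hz Named vector of fatigue-induced median shifts in Hz
#'   (negative = fatigue) per sEMG channel.
#' @param region_mean_peaks_gf Named vector of prefatigue mean peak
#'   pressures (gf) per pressure channel.
#' @param fatigue_factors Named vector of multiplicative post/pre factors
#'   per pressure channel.
#' @param step_rate_hz Gait cadence in steps per second (default 1).
#' @param between_subject_cv Log-normal CV of subject-level region-mean
#'   multipliers (default 0.35, matching the printed SD/mean ratios).
#' @param within_subject_cv Per-step amplitude CV (default 0.10).
#' @param mdf_subject_sd_hz SD of the additive subject MDF offset
#'   (default 15 Hz).
#' @param emg_amplitude_mv sEMG RMS amplitude in mV (default 0.1).
#' @param rpe_mean,rpe_sd Borg RPE score means/SDs per muscle group
#'   (defaults 14.3 (1.3) gastrocnemius, 7.0 (1.3) rectus femoris).
#' @param seed Integer master seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_subjects = 12,
    emg_rate_hz = 2000,
    pressure_rate_hz = 100,
    trial_duration_s = 10,
    n_trials = 3,
    emg_band_pre = list(
      emg_L_GA = c(20, 2 * 93.6 - 20),
      emg_R_GA = c(20, 2 * 81.3 - 20),
      emg_L_RF = c(20, 160),
      emg_R_RF = c(20, 160)
    ),
    mdf_shift_hz = c(emg_L_GA = -7.5, emg_R_GA = -9.2,
                     emg_L_RF = 0, emg_R_RF = 0),
    region_mean_peaks_gf = c(
      prs_L_HA = 900.7, prs_R_HA = 883.2,
      prs_L_LT = 435.6, prs_R_LT = 325.8,
      prs_L_M1 = 1100,  prs_R_M1 = 1100,
      prs_L_M5 = 500,   prs_R_M5 = 500,
      prs_L_ARCH = 300, prs_R_ARCH = 300,
      prs_L_MH = 1265.5, prs_R_MH = 1343.4
    ),
    fatigue_factors = c(
      prs_L_HA = 0.680, prs_R_HA = 0.674,
      prs_L_LT = 0.661, prs_R_LT = 0.687,
      prs_L_M1 = 1, prs_R_M1 = 1,
      prs_L_M5 = 1, prs_R_M5 = 1,
      prs_L_ARCH = 1, prs_R_ARCH = 1,
      prs_L_MH = 1.110, prs_R_MH = 1.072
    ),
    step_rate_hz = 1,
    between_subject_cv = 0.35,
    within_subject_cv = 0.10,
    mdf_subject_sd_hz = 15,
    emg_amplitude_mv = 0.1,
    rpe_mean = c(GA = 14.3, RF = 7.0),
    rpe_sd = c(GA = 1.3, RF = 1.3),
    seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), emg_rate_hz = emg_rate_hz,
    pressure_rate_hz = pressure_rate_hz,
    trial_duration_s = trial_duration_s, n_trials = as.integer(n_trials),
    emg_band_pre = emg_band_pre, mdf_shift_hz = mdf_shift_hz,
    region_mean_peaks_gf = region_mean_peaks_gf,
    fatigue_factors = fatigue_factors, step_rate_hz = step_rate_hz,
    between_subject_cv = between_subject_cv,
    within_subject_cv = within_subject_cv,
    mdf_subject_sd_hz = mdf_subject_sd_hz,
    emg_amplitude_mv = emg_amplitude_mv,
    rpe_mean = rpe_mean, rpe_sd = rpe_sd, seed = as.integer(seed),
    condition = "pre"
  )
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(
    cfg$n_subjects >= 1, cfg$emg_rate_hz > 0, cfg$pressure_rate_hz > 0,
    cfg$trial_duration_s > 0, cfg$n_trials >= 1, cfg$step_rate_hz > 0,
    cfg$between_subject_cv >= 0, cfg$within_subject_cv >= 0,
    cfg$mdf_subject_sd_hz >= 0
  )
  for (b in cfg$emg_band_pre) {
    if (!(b[1] > 0 && b[1] < b[2] && b[2] < cfg$emg_rate_hz / 2)) {
      stop("parameter error: sEMG band must satisfy 0 < low < high < Nyquist",
           call. = FALSE)
    }
  }
  if (any(cfg$region_mean_peaks_gf <= 0)) {
    stop("parameter error: region mean peaks must be positive", call. = FALSE)
  }
  if (any(cfg$fatigue_factors <= 0)) {
    stop("parameter error: fatigue factors must be positive", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic_config> %d subjects x %d trials x %g s (%s condition), seed %d\n",
    x$n_subjects, x$n_trials, x$trial_duration_s, x$condition, x$seed))
  invisible(x)
}

#' Generate band-limited Gaussian noise emulating sEMG
#'
#' White Gaussian noise is shaped in the frequency domain to have flat
#' power inside `band` and zero outside, so the analytic spectral median
#' is exactly `(low + high) / 2`. The result is rescaled to the requested
#' RMS amplitude.
#'
#' @param duration_s Duration in seconds.
#' @param rate_hz Sampling rate in Hz.
#' @param band `c(low, high)` passband in Hz, inside (0, Nyquist).
#' @param amplitude RMS amplitude (default 1).
#' @param seed Optional integer seed (RNG state is restored afterwards);
#'   `NULL` draws from the current stream.
#' @param label Channel label.
#' @param shape `"flat"` (default; analytic median `(low + high) / 2`) or
#'   `"pink"` (1/f-sloped in-band power for realism; no closed-form
#'   median, so not used in calibrated simulations).
#' @return A [sampled_signal()].
#' @export
#' @examples
#' s <- generate_semg(2, 2000, c(20, 500), seed = 1)
generate_semg <- function(duration_s, rate_hz, band, amplitude = 1,
                          seed = NULL, label = "emg",
                          shape = c("flat", "pink")) {
  shape <- match.arg(shape)
  low <- band[1]; high <- band[2]
  if (!(low > 0 && low < high && high < rate_hz / 2)) {
    stop("parameter error: band must satisfy 0 < low < high < Nyquist (",
         rate_hz / 2, " Hz)", call. = FALSE)
  }
  n <- round(duration_s * rate_hz)
  gen <- function() {
    x <- stats::rnorm(n)
    X <- stats::fft(x)
    freqs <- (seq_len(n) - 1L) * rate_hz / n
    # two-sided mask: keep [low, high] and its negative-frequency mirror
    fpos <- pmin(freqs, rate_hz - freqs)
    X[fpos < low | fpos > high] <- 0
    if (shape == "pink") {
      keep <- fpos >= low & fpos <= high
      X[keep] <- X[keep] / sqrt(fpos[keep])  # power ~ 1/f in band
    }
    y <- Re(stats::fft(X, inverse = TRUE)) / n
    y * amplitude / sqrt(mean(y^2))
  }
  y <- if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
  sampled_signal(y, rate_hz, label)
}

#' Generate a periodic gait pressure channel
#'
#' A train of half-sine stance bursts at the step cadence. Burst duration
#' is `0.6 / step_rate_hz` seconds (60% stance at the default cadence);
#' per-step amplitudes are `mean_peak_gf * (1 + noise_cv * N(0,1))`,
#' truncated at zero, so the signal is non-negative everywhere. The phase
#' offset mimics heel-to-toe roll-off (heel earliest, toes latest).
#'
#' @param duration_s Duration in seconds.
#' @param rate_hz Sampling rate in Hz.
#' @param mean_peak_gf Mean step peak amplitude in gram-force, > 0.
#' @param step_rate_hz Steps per second; `step_rate_hz * duration_s >= 1`.
#' @param phase_offset_s Burst onset delay within the stride, seconds.
#' @param noise_cv Per-step amplitude coefficient of variation.
#' @param seed Optional integer seed; `NULL` draws from the current stream.
#' @param label Channel label.
#' @return A [sampled_signal()].
#' @export
generate_pressure_channel <- function(duration_s, rate_hz, mean_peak_gf,
                                      step_rate_hz = 1, phase_offset_s = 0,
                                      noise_cv = 0, seed = NULL,
                                      label = "prs") {
  if (mean_peak_gf <= 0 || duration_s <= 0 || rate_hz <= 0 ||
      step_rate_hz <= 0 || phase_offset_s < 0 || noise_cv < 0) {
    stop("parameter error: all amplitudes, rates and durations must be ",
         "positive and offsets/CVs non-negative", call. = FALSE)
  }
  if (step_rate_hz * duration_s < 1) {
    stop("parameter error: duration too short for a single step",
         call. = FALSE)
  }
  n <- round(duration_s * rate_hz)
  burst_s <- 0.6 / step_rate_hz
  stride_s <- 1 / step_rate_hz
  starts <- seq(phase_offset_s, duration_s - burst_s, by = stride_s)
  if (length(starts) == 0L) {
    stop("parameter error: phase offset leaves no room for a burst",
         call. = FALSE)
  }
  gen <- function() {
    amps <- pmax(0, mean_peak_gf * (1 + noise_cv * stats::rnorm(length(starts))))
    x <- numeric(n)
    nb <- round(burst_s * rate_hz)
    shape <- sin(pi * (seq_len(nb) - 0.5) / nb)
    for (k in seq_along(starts)) {
      i0 <- round(starts[k] * rate_hz) + 1L
      idx <- i0:min(n, i0 + nb - 1L)
      x[idx] <- pmax(x[idx], amps[k] * shape[seq_along(idx)])
    }
    x
  }
  y <- if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
  sampled_signal(y, rate_hz, label)
}

# Stance onset offsets (seconds at 1 step/s) mimicking heel-to-toe
# roll-off; scaled with cadence. Convention, not an empirical claim.
region_phase_offsets <- function(step_rate_hz = 1) {
  base <- c(HA = 0.24, LT = 0.24, M1 = 0.16, M5 = 0.16, ARCH = 0.08,
            MH = 0)
  base / step_rate_hz
}

#' Derive the post-fatigue configuration
#'
#' Returns a copy of `config` describing the post-fatigue condition:
#' region mean peaks are multiplied by their fatigue factors and each
#' sEMG band's upper edge is lowered (lower edge kept) so the analytic
#' median `(low + high) / 2` moves by the configured shift.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_config` for the post condition.
#' @export
#' @examples
#' post <- apply_fatigue(synthetic_config())
#' post$region_mean_peaks_gf[["prs_R_HA"]]  # 883.2 * 0.674
apply_fatigue <- function(config) {
  validate_synthetic_config(config)
  post <- config
  post$region_mean_peaks_gf <-
    config$region_mean_peaks_gf * config$fatigue_factors[names(config$region_mean_peaks_gf)]
  for (ch in names(post$emg_band_pre)) {
    shift <- config$mdf_shift_hz[[ch]]
    b <- post$emg_band_pre[[ch]]
    b[2] <- b[2] + 2 * shift  # median = (low + high) / 2
    if (b[2] <= b[1]) {
      stop("parameter error: fatigue shift collapses the sEMG band for ", ch,
           call. = FALSE)
    }
    post$emg_band_pre[[ch]] <- b
  }
  post$condition <- "post"
  post
}

# Subject-level random effects: log-normal multipliers (mean 1) for the
# region means, additive Gaussian offsets for the per-muscle MDF. Drawn
# from the current RNG stream.
draw_subject_params <- function(config) {
  cv <- config$between_subject_cv
  sdlog <- sqrt(log(1 + cv^2))
  regions <- names(config$region_mean_peaks_gf)
  muscles <- names(config$emg_band_pre)
  lapply(seq_len(config$n_subjects), function(s) {
    mult <- if (cv > 0) {
      stats::rlnorm(length(regions), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, length(regions))
    names(mult) <- regions
    off <- stats::rnorm(length(muscles), 0, config$mdf_subject_sd_hz)
    names(off) <- muscles
    list(region_mult = mult, mdf_offset_hz = off)
  })
}

# Clamp a subject's band so it stays inside the 20-500 Hz analysis band
# and keeps a minimal width.
subject_band <- function(band, offset_hz) {
  b <- band + c(0, 2 * offset_hz)
  b[2] <- min(max(b[2], b[1] + 10), 500)
  b
}

#' Generate a full synthetic pre/post cohort
#'
#' For each subject, subject-level random effects are drawn (log-normal
#' region-mean multipliers, additive MDF offsets); then `n_trials`
#' recordings per condition are generated. Each trial yields two
#' [recording()] objects — one with the 4 sEMG channels at the sEMG rate
#' and one with the 12 pressure channels at the pressure rate — because a
#' recording's channels must share one sampling rate. Deterministic given
#' `config$seed`.
#'
#' @param config A [synthetic_config()] (the pre-fatigue state; the post
#'   state is derived internally with [apply_fatigue()]).
#' @param modalities Which modalities to generate, a subset of
#'   `c("emg", "pressure")`; restricting to one modality speeds up large
#'   simulation studies that only exercise one arm of the analysis.
#' @return A list of `recording` objects
#'   (`n_subjects * 2 conditions * n_trials * length(modalities)`), with
#'   the config and drawn subject parameters attached as attributes
#'   `config` and `subject_params`.
#' @export
generate_cohort <- function(config, modalities = c("emg", "pressure")) {
  modalities <- match.arg(modalities, several.ok = TRUE)
  validate_synthetic_config(config)
  post_cfg <- apply_fatigue(config)
  phase <- region_phase_offsets(config$step_rate_hz)
  withr::with_seed(config$seed, {
    subj <- draw_subject_params(config)
    out <- vector("list", 0L)
    for (s in seq_len(config$n_subjects)) {
      sid <- sprintf("S%02d", s)
      for (cond in c("pre", "post")) {
        cfg <- if (cond == "pre") config else post_cfg
        for (k in seq_len(config$n_trials)) {
          if ("emg" %in% modalities) {
            emg_sigs <- lapply(names(cfg$emg_band_pre), function(ch) {
              b <- subject_band(cfg$emg_band_pre[[ch]],
                                subj[[s]]$mdf_offset_hz[[ch]])
              generate_semg(cfg$trial_duration_s, cfg$emg_rate_hz, b,
                            amplitude = cfg$emg_amplitude_mv, label = ch)
            })
            names(emg_sigs) <- names(cfg$emg_band_pre)
            out[[length(out) + 1L]] <- recording(emg_sigs, cond, sid, k)
          }
          if ("pressure" %in% modalities) {
            prs_sigs <- lapply(names(cfg$region_mean_peaks_gf), function(ch) {
              reg <- sub("^prs_[LR]_", "", ch)
              amp <- cfg$region_mean_peaks_gf[[ch]] * subj[[s]]$region_mult[[ch]]
              generate_pressure_channel(
                cfg$trial_duration_s, cfg$pressure_rate_hz, amp,
                step_rate_hz = cfg$step_rate_hz,
                phase_offset_s = phase[[reg]],
                noise_cv = cfg$within_subject_cv, label = ch)
            })
            names(prs_sigs) <- names(cfg$region_mean_peaks_gf)
            out[[length(out) + 1L]] <- recording(prs_sigs, cond, sid, k)
          }
        }
      }
    }
    attr(out, "config") <- config
    attr(out, "subject_params") <- subj
    out
  })
}

#' Draw Borg RPE scores for a synthetic cohort
#'
#' Integer scores per subject and muscle group, normal around the
#' configured means, rounded and clamped to the Borg 6-20 range.
#'
#' @param config A [synthetic_config()].
#' @param n Number of subjects (defaults to `config$n_subjects`).
#' @return Data frame with columns `subject_id`, `muscle`, `score`.
#' @export
generate_rpe <- function(config, n = config$n_subjects) {
  withr::with_seed(config$seed + 1L, {
    rows <- lapply(names(config$rpe_mean), function(m) {
      sc <- round(stats::rnorm(n, config$rpe_mean[[m]], config$rpe_sd[[m]]))
      data.frame(subject_id = sprintf("S%02d", seq_len(n)), muscle = m,
                 score = pmin(20, pmax(6, sc)), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
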