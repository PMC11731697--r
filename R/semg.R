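# sEMG median-frequency fatigue analysis:
# 20-500 Hz FIR bandpass -> power spectrum (FFT) -> median frequency,
# averaged over the three consecutive trials of a condition.

# Windowed-sinc (Hamming) bandpass coefficients. Odd tap count gives a
# type-I linear-phase filter so centered application is zero-phase.
fir_bandpass_coefs <- function(rate_hz, low_hz, high_hz,
                               order = NULL) {
  if (is.null(order)) order <- 2L * ceiling(2 * rate_hz / low_hz)
  ntaps <- as.integer(order) + 1L
  m <- (ntaps - 1L) / 2L
  n <- seq_len(ntaps) - 1L - m
  fl <- low_hz / rate_hz
  fh <- high_hz / rate_hz
  h <- ifelse(n == 0, 2 * (fh - fl),
              (sin(2 * pi * fh * n) - sin(2 * pi * fl * n)) / (pi * n))
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(ntaps - 1L)) / (ntaps - 1L))
  h <- h * w
  # normalize unit gain at the passband center
  fc <- (low_hz + high_hz) / 2
  g <- Mod(sum(h * exp(-2i * pi * fc / rate_hz * (0:(ntaps - 1L)))))
  h / g
}

# Same-length, zero-phase application of a symmetric FIR by centered full
# convolution with reflected edge padding.
fir_apply_same <- function(x, h) {
  L <- length(h)
  half <- (L - 1L) / 2L
  n <- length(x)
  xp <- c(2 * x[1] - x[(half + 1L):2L], x,
          2 * x[n] - x[(n - 1L):(n - half)])
  y <- stats::convolve(xp, rev(h), type = "open")
  y[L:(L + n - 1L)]
}

#' Zero-phase FIR bandpass filter
#'
#' Windowed-sinc (Hamming) bandpass with order `4 * rate_hz / low_hz`
#' rounded to even, applied forward-backward (two centered passes of the
#' symmetric kernel) for zero phase. The default 20-500 Hz band is the
#' standard sEMG preprocessing band.
#'
#' @param signal A [sampled_signal()].
#' @param low_hz,high_hz Passband edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < rate_hz / 2`.
#' @return A filtered [sampled_signal()] of equal length and rate.
#' @export
#' @examples
#' s <- sampled_signal(sin(2 * pi * 100 * (0:3999) / 2000), 2000, "tone")
#' f <- bandpass_fir(s)
bandpass_fir <- function(signal, low_hz = 20, high_hz = 500) {
  stopifnot(inherits(signal, "sampled_signal"))
  rate <- signal$rate_hz
  if (!(low_hz > 0 && low_hz < high_hz)) {
    stop("parameter error: need 0 < low_hz < high_hz", call. = FALSE)
  }
  if (high_hz >= rate / 2) {
    stop("parameter error: high_hz must be below the Nyquist frequency ",
         rate / 2, " Hz", call. = FALSE)
  }
  h <- fir_bandpass_coefs(rate, low_hz, high_hz)
  if (length(signal$samples) <= length(h)) {
    stop(sprintf(
      "length error: signal (%d samples) must be longer than the filter (%d taps)",
      length(signal$samples), length(h)), call. = FALSE)
  }
  y <- fir_apply_same(fir_apply_same(signal$samples, h), h)
  sampled_signal(y, rate, signal$label)
}

#' Power spectrum of a sampled signal
#'
#' One-sided power spectral estimate normalized so that the summed power
#' equals the time-domain mean square (Parseval). The Welch estimate is
#' rescaled to the signal's exact total power after averaging — the
#' spectral shape (and hence the median frequency, which is invariant
#' under uniform power scaling) is untouched. The default estimator is Welch
#' averaging with 1-second Hann-windowed segments and 50% overlap, which
#' stabilizes the median-frequency estimate on stochastic sEMG; a plain
#' single-window periodogram is available via `method`.
#'
#' @param signal A [sampled_signal()] with at least 256 samples.
#' @param method `"welch"` (default) or `"periodogram"`.
#' @param segment_s Welch segment length in seconds (default 1).
#' @param overlap Welch fractional overlap in `[0, 1)` (default 0.5).
#' @return An object of class `power_spectrum` with fields `freqs_hz`
#'   (ascending), `power` (non-negative, same length) and `resolution_hz`.
#' @export
power_spectrum <- function(signal, method = c("welch", "periodogram"),
                           segment_s = 1, overlap = 0.5) {
  stopifnot(inherits(signal, "sampled_signal"))
  method <- match.arg(method)
  x <- signal$samples
  n <- length(x)
  if (n < 256L) {
    stop("signal too short for spectral analysis (need >= 256 samples)",
         call. = FALSE)
  }
  rate <- signal$rate_hz
  if (method == "periodogram") {
    spec <- one_sided_periodogram(x, rep(1, n))
  } else {
    nseg <- min(n, max(256L, round(segment_s * rate)))
    step <- max(1L, floor(nseg * (1 - overlap)))
    starts <- seq(1L, n - nseg + 1L, by = step)
    w <- 0.5 - 0.5 * cos(2 * pi * (0:(nseg - 1L)) / (nseg - 1L))  # Hann
    acc <- NULL
    for (s0 in starts) {
      p <- one_sided_periodogram(x[s0:(s0 + nseg - 1L)], w)
      acc <- if (is.null(acc)) p else acc + p
    }
    spec <- acc / length(starts)
    if (sum(spec) > 0) spec <- spec * (mean(x^2) / sum(spec))
    n <- nseg
  }
  total <- sum(spec)
  if (total <= 0) {
    stop("degenerate spectrum: total power is zero", call. = FALSE)
  }
  nfreq <- length(spec)
  freqs <- (seq_len(nfreq) - 1L) * rate / n
  structure(
    list(freqs_hz = freqs, power = spec, resolution_hz = rate / n),
    class = "power_spectrum"
  )
}

# |FFT(w x)|^2 / (N * sum(w^2)), folded to one side so that the summed
# one-sided power estimates mean(x^2).
one_sided_periodogram <- function(x, w) {
  n <- length(x)
  X <- stats::fft(x * w)
  p <- Mod(X)^2 / (n * sum(w^2))
  half <- floor(n / 2) + 1L
  one <- p[seq_len(half)]
  if (n %% 2 == 0) {
    if (half > 2L) one[2:(half - 1L)] <- 2 * one[2:(half - 1L)]
  } else {
    one[2:half] <- 2 * one[2:half]
  }
  one
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf(
    "<power_spectrum> %d bins, 0-%.1f Hz, resolution %.3g Hz, total power %.4g\n",
    length(x$power), max(x$freqs_hz), x$resolution_hz, sum(x$power)))
  invisible(x)
}

#' Median frequency of a power spectrum
#'
#' The median frequency (MDF) splits the power spectrum into two regions
#' of equal summed power. The discrete-bin convention used here returns
#' the smallest bin frequency whose cumulative power reaches at least half
#' the total (ties resolved toward the lower frequency; no interpolation).
#' A downward MDF shift between conditions indicates localized muscle
#' fatigue.
#'
#' @param spectrum A `power_spectrum` (see [power_spectrum()]), or any list
#'   with numeric `freqs_hz` and `power`.
#' @return The median frequency in Hz.
#' @export
#' @examples
#' sp <- structure(list(freqs_hz = c(50, 150), power = c(3, 1)),
#'                 class = "power_spectrum")
#' median_frequency(sp)  # 50
median_frequency <- function(spectrum) {
  p <- spectrum$power
  f <- spectrum$freqs_hz
  if (length(p) != length(f) || is.unsorted(f, strictly = TRUE)) {
    stop("spectrum must have strictly ascending freqs_hz matching power",
         call. = FALSE)
  }
  if (any(p < 0)) stop("spectral power must be non-negative", call. = FALSE)
  total <- sum(p)
  if (total <= 0) {
    stop("degenerate spectrum: total power is zero", call. = FALSE)
  }
  idx <- which(cumsum(p) >= total / 2)[1]
  f[idx]
}

#' Condition-level MDF from repeated trials
#'
#' Applies [bandpass_fir()], [power_spectrum()] and [median_frequency()]
#' to each trial and averages the per-trial MDFs (the three consecutive
#' signals of a condition are averaged at the MDF level).
#'
#' @param trials List of [sampled_signal()] objects sharing one rate.
#' @param muscle Muscle channel label (e.g. `"emg_L_GA"`).
#' @param condition `"pre"` or `"post"`.
#' @param low_hz,high_hz Filter band passed to [bandpass_fir()].
#' @param method Spectrum estimator passed to [power_spectrum()].
#' @param rectify If `TRUE`, full-wave rectify the filtered signal before
#'   the FFT. Off by default: rectification distorts the spectrum whose
#'   median is the fatigue index, so the default analyzes the filtered
#'   raw signal.
#' @param aggregate `"mdf"` (default) averages the per-trial median
#'   frequencies; `"spectrum"` averages the per-trial spectra first and
#'   takes the median frequency of the average.
#' @return An object of class `mdf_result`: `mdf_hz`, per-trial values,
#'   `muscle`, `condition`, `n_trials_averaged`.
#' @export
mdf_for_condition <- function(trials, muscle, condition = c("pre", "post"),
                              low_hz = 20, high_hz = 500,
                              method = c("welch", "periodogram"),
                              rectify = FALSE,
                              aggregate = c("mdf", "spectrum")) {
  condition <- match.arg(condition)
  method <- match.arg(method)
  aggregate <- match.arg(aggregate)
  if (length(trials) == 0L) {
    stop("input error: at least one trial is required", call. = FALSE)
  }
  rates <- vapply(trials, function(s) s$rate_hz, numeric(1))
  if (length(unique(rates)) != 1L) {
    stop("input error: all trials must share rate_hz", call. = FALSE)
  }
  spectra <- lapply(trials, function(s) {
    filt <- bandpass_fir(s, low_hz = low_hz, high_hz = high_hz)
    if (rectify) filt$samples <- abs(filt$samples)
    power_spectrum(filt, method = method)
  })
  per_trial <- vapply(spectra, median_frequency, numeric(1))
  mdf <- if (aggregate == "mdf") {
    mean(per_trial)
  } else {
    avg <- spectra[[1]]
    avg$power <- Reduce(`+`, lapply(spectra, `[[`, "power")) / length(spectra)
    median_frequency(avg)
  }
  structure(
    list(mdf_hz = mdf, per_trial_mdf_hz = per_trial,
         muscle = muscle, condition = condition,
         n_trials_averaged = length(trials)),
    class = "mdf_result"
  )
}

#' @export
print.mdf_result <- function(x, ...) {
  cat(sprintf("<mdf_result> %s (%s): MDF %.1f Hz over %d trial(s)\n",
              x$muscle, x$condition, x$mdf_hz, x$n_trials_averaged))
  invisible(x)
}

#' Pre-to-post MDF shift
#'
#' Returns `post - pre` in Hz; a negative value is the fatigue direction
#' (spectral compression toward lower frequencies).
#'
#' @param pre,post `mdf_result` objects for the same muscle.
#' @return Signed shift in Hz.
#' @export
fatigue_shift <- function(pre, post) {
  if (!identical(pre$muscle, post$muscle)) {
    stop("input error: pre and post MDF results refer to different muscles (",
         pre$muscle, " vs ", post$muscle, ")", call. = FALSE)
  }
  post$mdf_hz - pre$mdf_hz
}
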