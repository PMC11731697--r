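#' @keywords internal
"_PACKAGE"

# Channel vocabulary -----------------------------------------------------

#' Anatomical region and muscle labels
#'
#' Six plantar regions are monitored per foot: hallux (`HA`), lesser toes
#' (`LT`), first metatarsal (`M1`), fifth metatarsal (`M5`), midfoot arch
#' (`ARCH`) and medial heel (`MH`). Two muscles carry sEMG electrodes per
#' leg: gastrocnemius (`GA`) and rectus femoris (`RF`). Channels are named
#' `<modality>_<side>_<label>`, e.g. `prs_L_HA` or `emg_R_GA`.
#'
#' @format Character vectors of labels.
#' @name channel-labels
NULL

#' @rdname channel-labels
#' @export
REGION_LABELS <- c("HA", "LT", "M1", "M5", "ARCH", "MH")

#' @rdname channel-labels
#' @export
MUSCLE_LABELS <- c("GA", "RF")

#' @rdname channel-labels
#' @export
SIDE_LABELS <- c("L", "R")

#' Build a channel identifier
#'
#' @param modality `"prs"` (plantar pressure) or `"emg"`.
#' @param side `"L"` or `"R"`.
#' @param label A region label (for pressure) or muscle label (for sEMG).
#' @return A channel id string such as `"prs_L_HA"`.
#' @export
#' @examples
#' channel_id("prs", "L", "HA")
channel_id <- function(modality, side, label) {
  modality <- match.arg(modality, c("prs", "emg"))
  side <- match.arg(side, SIDE_LABELS)
  if (modality == "prs") label <- match.arg(label, REGION_LABELS)
  else label <- match.arg(label, MUSCLE_LABELS)
  paste(modality, side, label, sep = "_")
}

#' All pressure / sEMG channel ids for both sides
#' @return Character vector of 12 pressure or 4 sEMG channel ids.
#' @export
pressure_channels <- function() {
  as.vector(t(outer(SIDE_LABELS, REGION_LABELS,
                    function(s, r) paste("prs", s, r, sep = "_"))))
}

#' @rdname pressure_channels
#' @export
emg_channels <- function() {
  as.vector(t(outer(SIDE_LABELS, MUSCLE_LABELS,
                    function(s, m) paste("emg", s, m, sep = "_"))))
}

# SampledSignal ----------------------------------------------------------

#' Construct a uniformly sampled signal
#'
#' A `sampled_signal` is the package's basic time-series container: an
#' ordered numeric vector with a sampling rate and a channel label.
#' Units are millivolt-scale for sEMG and gram-force (gf) for pressure;
#' the container does not convert units.
#'
#' @param samples Numeric vector, all finite, length >= 1.
#' @param rate_hz Positive sampling rate in Hz.
#' @param label Channel identifier string.
#' @return An object of class `sampled_signal` with fields `samples`,
#'   `rate_hz` and `label`.
#' @export
#' @examples
#' s <- sampled_signal(sin(2 * pi * 5 * seq(0, 1, by = 1 / 100)), 100, "demo")
#' s
sampled_signal <- function(samples, rate_hz, label = "signal") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("signal must contain at least one sample", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("signal samples must all be finite", call. = FALSE)
  }
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0) {
    stop("rate_hz must be a single positive number", call. = FALSE)
  }
  structure(
    list(samples = samples, rate_hz = as.numeric(rate_hz),
         label = as.character(label)),
    class = "sampled_signal"
  )
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %s: %d samples @ %g Hz (%.3f s)\n",
              x$label, length(x$samples), x$rate_hz,
              length(x$samples) / x$rate_hz))
  invisible(x)
}

#' @export
length.sampled_signal <- function(x) length(x$samples)

#' Signal duration in seconds
#' @param x A [sampled_signal()].
#' @return Duration in seconds.
#' @export
signal_duration <- function(x) length(x$samples) / x$rate_hz

# Recording --------------------------------------------------------------

#' Construct a multi-channel recording
#'
#' Bundles the channels of one measurement trial. All channels in one
#' recording must share the sampling rate; sEMG (2000 Hz) and pressure
#' (100 Hz) channels therefore live in separate recordings.
#'
#' @param signals Named list of [sampled_signal()] objects (names are
#'   channel ids).
#' @param condition `"pre"` or `"post"` (fatigue condition).
#' @param subject_id Subject identifier string.
#' @param trial_index Integer trial number, >= 1.
#' @return An object of class `recording`.
#' @export
recording <- function(signals, condition = c("pre", "post"),
                      subject_id = "S01", trial_index = 1L) {
  condition <- match.arg(condition)
  if (!is.list(signals) || length(signals) == 0L) {
    stop("signals must be a non-empty named list", call. = FALSE)
  }
  if (is.null(names(signals)) || anyDuplicated(names(signals))) {
    stop("signals must have unique names (channel ids)", call. = FALSE)
  }
  ok <- vapply(signals, inherits, logical(1), what = "sampled_signal")
  if (!all(ok)) stop("all signals must be sampled_signal objects", call. = FALSE)
  rates <- vapply(signals, function(s) s$rate_hz, numeric(1))
  if (length(unique(rates)) != 1L) {
    stop("all signals in a recording must share rate_hz", call. = FALSE)
  }
  trial_index <- as.integer(trial_index)
  if (trial_index < 1L) stop("trial_index must be >= 1", call. = FALSE)
  structure(
    list(signals = signals, rate_hz = rates[[1]], condition = condition,
         subject_id = as.character(subject_id), trial_index = trial_index),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> subject %s, %s, trial %d: %d channels @ %g Hz\n",
    x$subject_id, x$condition, x$trial_index, length(x$signals), x$rate_hz))
  cat("  channels:", paste(names(x$signals), collapse = ", "), "\n")
  invisible(x)
}
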