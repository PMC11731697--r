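# Plantar-pressure peak analysis: segment gait steps by relative-threshold
# crossing, pool per-step peak pressures across trials, summarize per
# anatomical region for pre/post comparison.

#' Detect gait steps in a pressure channel
#'
#' Contiguous intervals above `threshold_frac` times the global maximum
#' become step events; neighbouring intervals separated by less than
#' `min_separation_s` are merged (they belong to the same stance). The
#' relative threshold makes detection invariant to uniform sensor scaling.
#'
#' @param signal A [sampled_signal()]; gait-rate sampling (>= 50 Hz)
#'   recommended.
#' @param threshold_frac Fraction of the global maximum in (0, 1);
#'   default 0.2.
#' @param min_separation_s Minimum inter-step gap in seconds; default 0.4.
#' @return A data frame of class `step_events` with one row per step:
#'   `start`, `end` (half-open sample interval, 1-based), `peak_index`,
#'   `peak_value`. An all-zero or all-subthreshold signal yields zero rows.
#' @export
detect_steps <- function(signal, threshold_frac = 0.2,
                         min_separation_s = 0.4) {
  stopifnot(inherits(signal, "sampled_signal"))
  if (!(threshold_frac > 0 && threshold_frac < 1)) {
    stop("threshold_frac must be strictly between 0 and 1", call. = FALSE)
  }
  x <- signal$samples
  if (!all(is.finite(x))) {
    stop("input error: non-finite samples in ", signal$label, call. = FALSE)
  }
  empty <- data.frame(start = integer(), end = integer(),
                      peak_index = integer(), peak_value = numeric())
  class(empty) <- c("step_events", "data.frame")
  mx <- max(x)
  if (mx <= 0) return(empty)
  thr <- threshold_frac * mx
  above <- x >= thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends_at <- cumsum(r$lengths)
  starts_at <- ends_at - r$lengths + 1L
  runs <- data.frame(start = starts_at[r$values], end = ends_at[r$values] + 1L)
  # merge runs whose gap is shorter than the minimum step separation
  min_gap <- min_separation_s * signal$rate_hz
  if (nrow(runs) > 1L) {
    keep_start <- runs$start[1]
    merged <- list()
    for (i in seq_len(nrow(runs) - 1L)) {
      if (runs$start[i + 1L] - runs$end[i] < min_gap) next
      merged[[length(merged) + 1L]] <- c(keep_start, runs$end[i])
      keep_start <- runs$start[i + 1L]
    }
    merged[[length(merged) + 1L]] <- c(keep_start, runs$end[nrow(runs)])
    runs <- as.data.frame(do.call(rbind, merged))
    names(runs) <- c("start", "end")
  }
  peak_index <- integer(nrow(runs))
  peak_value <- numeric(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    seg <- runs$start[i]:(runs$end[i] - 1L)
    peak_index[i] <- seg[which.max(x[seg])]
    peak_value[i] <- x[peak_index[i]]
  }
  out <- data.frame(start = as.integer(runs$start),
                    end = as.integer(runs$end),
                    peak_index = peak_index, peak_value = peak_value)
  class(out) <- c("step_events", "data.frame")
  out
}

#' Mean peak pressure for one region over repeated trials
#'
#' Detects steps in each trial and pools the per-step peak values across
#' steps and trials before averaging (maximizing the sample at small n).
#' Trials yielding no steps are skipped with a warning; if no trial yields
#' a step the summary is an error, not a fabricated zero.
#'
#' @param trials List of [sampled_signal()] objects (same region channel,
#'   consecutive trials of one condition).
#' @param region Region channel label (e.g. `"prs_R_HA"`).
#' @param condition `"pre"` or `"post"`.
#' @param threshold_frac,min_separation_s Passed to [detect_steps()].
#' @param pooling `"steps"` (default) averages the peak values of all
#'   steps pooled across trials; `"trials"` first averages per trial,
#'   then averages the trial means.
#' @return An object of class `region_peak_summary`: `region`, `condition`,
#'   `mean_peak_gf`, `sd_peak_gf` (n-1 denominator; 0 for a single step),
#'   `n_steps`, `n_trials`, and the pooled `peaks`.
#' @export
mean_peak_pressure <- function(trials, region, condition = c("pre", "post"),
                               threshold_frac = 0.2, min_separation_s = 0.4,
                               pooling = c("steps", "trials")) {
  condition <- match.arg(condition)
  pooling <- match.arg(pooling)
  if (length(trials) == 0L) {
    stop("input error: at least one trial is required", call. = FALSE)
  }
  peaks <- numeric(0)
  trial_means <- numeric(0)
  used <- 0L
  for (tr in trials) {
    ev <- detect_steps(tr, threshold_frac = threshold_frac,
                       min_separation_s = min_separation_s)
    if (nrow(ev) == 0L) {
      warning("no steps detected in a trial of ", region, " (", condition,
              "); trial skipped", call. = FALSE)
      next
    }
    peaks <- c(peaks, ev$peak_value)
    trial_means <- c(trial_means, mean(ev$peak_value))
    used <- used + 1L
  }
  if (length(peaks) == 0L) {
    stop("empty summary: no usable steps in any trial of ", region,
         call. = FALSE)
  }
  vals <- if (pooling == "steps") peaks else trial_means
  structure(
    list(region = region, condition = condition,
         mean_peak_gf = mean(vals),
         sd_peak_gf = if (length(vals) > 1L) stats::sd(vals) else 0,
         n_steps = length(peaks), n_trials = used, peaks = peaks),
    class = "region_peak_summary"
  )
}

#' @export
print.region_peak_summary <- function(x, ...) {
  cat(sprintf(
    "<region_peak_summary> %s (%s): mean peak %.1f gf (SD %.1f), %d steps / %d trials\n",
    x$region, x$condition, x$mean_peak_gf, x$sd_peak_gf, x$n_steps,
    x$n_trials))
  invisible(x)
}

#' Percent change from pre to post
#'
#' `100 * (post - pre) / pre`; negative values are decreases, matching the
#' reporting convention for fatigue-induced load redistribution.
#'
#' @param pre_mean,post_mean Group means; `pre_mean` must be non-zero.
#' @return Signed percent change.
#' @export
#' @examples
#' percent_change(883.2, 595.1)  # -32.6
percent_change <- function(pre_mean, post_mean) {
  if (any(pre_mean == 0)) {
    stop("division error: pre_mean must be non-zero", call. = FALSE)
  }
  100 * (post_mean - pre_mean) / pre_mean
}
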