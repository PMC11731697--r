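# Pre/post inference: closed-form paired t-test on subject-level values,
# per-region reporting at P < .05 without multiplicity correction, and
# Borg RPE descriptive summaries.

#' Paired t-test from its closed form
#'
#' For paired samples the statistic is `t = mean(d) / (sd(d) / sqrt(n))`
#' with `d = post - pre` and the n-1 SD; the two-sided p value comes from
#' the t distribution with `n - 1` degrees of freedom. A zero difference
#' variance raises a typed error rather than returning an infinite t.
#'
#' @param pre,post Numeric vectors of equal length `n >= 2` (one value per
#'   subject, paired by position).
#' @param alpha Significance level (default 0.05, two-sided).
#' @param label Comparison label carried into the result row.
#' @return A one-row data frame of class `paired_comparison`: `label`,
#'   `pre_mean`, `post_mean`, `pre_sd`, `post_sd`, `percent_change`,
#'   `t_stat`, `df`, `p_value`, `significant`.
#' @export
#' @examples
#' paired_t_test(c(1, 2, 3), c(1, 3, 5))  # t = sqrt(3), df = 2
paired_t_test <- function(pre, post, alpha = 0.05, label = "comparison") {
  if (length(pre) != length(post)) {
    stop("input error: pre and post must have equal length", call. = FALSE)
  }
  n <- length(pre)
  if (n < 2L) stop("input error: need at least 2 pairs", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  d <- post - pre
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    stop("degenerate-variance error: all paired differences are identical (",
         signif(d[1], 6), "); t is undefined", call. = FALSE)
  }
  t_stat <- mean(d) / (sd_d / sqrt(n))
  df <- n - 1L
  p <- 2 * stats::pt(-abs(t_stat), df)
  out <- data.frame(
    label = label,
    pre_mean = mean(pre), post_mean = mean(post),
    pre_sd = stats::sd(pre), post_sd = stats::sd(post),
    percent_change = if (mean(pre) != 0) percent_change(mean(pre), mean(post)) else NA_real_,
    t_stat = t_stat, df = df, p_value = p,
    significant = p < alpha,
    stringsAsFactors = FALSE
  )
  class(out) <- c("paired_comparison", "data.frame")
  out
}

# Shared pairing machinery: long data frames with subject_id / channel /
# value columns, one paired test per channel.
compare_paired_long <- function(pre, post, value_col, alpha = 0.05) {
  for (df in list(pre, post)) {
    if (!all(c("subject_id", "channel", value_col) %in% names(df))) {
      stop("input error: expected columns subject_id, channel, ", value_col,
           call. = FALSE)
    }
  }
  if (!setequal(unique(pre$subject_id), unique(post$subject_id))) {
    stop("pairing error: pre and post subject sets differ", call. = FALSE)
  }
  subjects <- sort(unique(pre$subject_id))
  channels <- sort(unique(pre$channel))
  rows <- lapply(channels, function(ch) {
    pv <- merge(
      pre[pre$channel == ch, c("subject_id", value_col)],
      post[post$channel == ch, c("subject_id", value_col)],
      by = "subject_id", suffixes = c("_pre", "_post")
    )
    if (nrow(pv) != length(subjects)) {
      stop("pairing error: channel ", ch,
           " is missing subjects in one condition", call. = FALSE)
    }
    paired_t_test(pv[[paste0(value_col, "_pre")]],
                  pv[[paste0(value_col, "_post")]],
                  alpha = alpha, label = ch)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired pre/post comparison of all plantar regions
#'
#' Runs one paired t-test per (region, side) channel — 12 in total — on
#' subject-level mean peak pressures. No multiple-testing correction is
#' applied by default; `correct = "holm"` is available.
#'
#' @param pre,post Data frames with columns `subject_id`, `channel`,
#'   `mean_peak_gf`: one row per subject and pressure channel.
#' @param alpha Significance level (default 0.05).
#' @param correct `"none"` (default) or `"holm"`.
#' @return A data frame of `paired_comparison` rows, one per channel.
#' @export
compare_all_regions <- function(pre, post, alpha = 0.05,
                                correct = c("none", "holm")) {
  correct <- match.arg(correct)
  out <- compare_paired_long(pre, post, "mean_peak_gf", alpha = alpha)
  if (correct == "holm") {
    out$p_value <- stats::p.adjust(out$p_value, method = "holm")
    out$significant <- out$p_value < alpha
  }
  out
}

#' Paired pre/post comparison of muscle median frequencies
#'
#' One paired t-test per sEMG channel (4 in total: gastrocnemius and
#' rectus femoris, both sides) on subject-level MDFs.
#'
#' @param pre,post Data frames with columns `subject_id`, `channel`,
#'   `mdf_hz`.
#' @param alpha Significance level (default 0.05).
#' @return A data frame of `paired_comparison` rows, one per channel.
#' @export
compare_all_muscles <- function(pre, post, alpha = 0.05) {
  compare_paired_long(pre, post, "mdf_hz", alpha = alpha)
}

#' Borg RPE descriptive summary
#'
#' Summarizes self-reported exertion on the Borg 6-20 scale for one
#' muscle group: mean and n-1 SD.
#'
#' @param scores Integer-valued scores, each within `[6, 20]`.
#' @param muscle Muscle label the scores refer to.
#' @return An object of class `rpe_summary`: `muscle`, `mean_score`,
#'   `sd_score`, `n`.
#' @export
#' @examples
#' rpe_summary(c(13, 14, 15), "GA")
rpe_summary <- function(scores, muscle) {
  if (length(scores) == 0L) stop("input error: no scores", call. = FALSE)
  if (any(scores < 6 | scores > 20)) {
    stop("validation error: Borg RPE scores must lie within [6, 20]",
         call. = FALSE)
  }
  structure(
    list(muscle = muscle, mean_score = mean(scores),
         sd_score = if (length(scores) > 1L) stats::sd(scores) else 0,
         n = length(scores)),
    class = "rpe_summary"
  )
}

#' @export
print.rpe_summary <- function(x, ...) {
  cat(sprintf("<rpe_summary> %s: %.1f (SD %.1f), n = %d\n",
              x$muscle, x$mean_score, x$sd_score, x$n))
  invisible(x)
}
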