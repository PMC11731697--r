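# Orchestration: cohort analysis in memory, cohort (de)serialization to a
# directory tree, and the simulate / analyze / report command front-end.

#' Analyze a pre/post cohort of recordings
#'
#' Runs the full analysis on a list of [recording()] objects (as produced
#' by [generate_cohort()] or [read_cohort()]): per subject and condition,
#' sEMG channels go through filter / spectrum / median frequency with the
#' per-trial MDFs averaged, and pressure channels through step detection
#' with peaks pooled across trials; paired t-tests then compare pre vs
#' post per channel.
#'
#' @param recordings List of `recording` objects covering both conditions.
#' @param alpha Significance level (default 0.05).
#' @param low_hz,high_hz sEMG filter band (defaults 20 / 500 Hz).
#' @param spectrum_method `"welch"` or `"periodogram"`.
#' @param threshold_frac,min_separation_s Step-detection parameters.
#' @return A list: `results` (data frame of paired comparisons — 12
#'   pressure regions then 4 muscles), `mdf` and `pressure` (subject-level
#'   long tables), `n_recordings`.
#' @export
analyze_cohort <- function(recordings, alpha = 0.05, low_hz = 20,
                           high_hz = 500,
                           spectrum_method = c("welch", "periodogram"),
                           threshold_frac = 0.2, min_separation_s = 0.4) {
  spectrum_method <- match.arg(spectrum_method)
  if (length(recordings) == 0L) {
    stop("input error: no recordings to analyze", call. = FALSE)
  }
  key <- vapply(recordings, function(r) {
    paste(r$subject_id, r$condition, sep = "|")
  }, character(1))
  mdf_rows <- list()
  prs_rows <- list()
  for (grp in unique(key)) {
    recs <- recordings[key == grp]
    parts <- strsplit(grp, "|", fixed = TRUE)[[1]]
    sid <- parts[1]; cond <- parts[2]
    channels <- unique(unlist(lapply(recs, function(r) names(r$signals))))
    for (ch in channels) {
      trials <- lapply(recs[vapply(recs, function(r) ch %in% names(r$signals),
                                   logical(1))],
                       function(r) r$signals[[ch]])
      if (startsWith(ch, "emg")) {
        res <- mdf_for_condition(trials, ch, cond, low_hz = low_hz,
                                 high_hz = high_hz, method = spectrum_method)
        mdf_rows[[length(mdf_rows) + 1L]] <- data.frame(
          subject_id = sid, condition = cond, channel = ch,
          mdf_hz = res$mdf_hz, n_trials = res$n_trials_averaged,
          stringsAsFactors = FALSE)
      } else {
        summ <- mean_peak_pressure(trials, ch, cond,
                                   threshold_frac = threshold_frac,
                                   min_separation_s = min_separation_s)
        prs_rows[[length(prs_rows) + 1L]] <- data.frame(
          subject_id = sid, condition = cond, channel = ch,
          mean_peak_gf = summ$mean_peak_gf, sd_peak_gf = summ$sd_peak_gf,
          n_steps = summ$n_steps, n_trials = summ$n_trials,
          stringsAsFactors = FALSE)
      }
    }
  }
  mdf <- if (length(mdf_rows)) do.call(rbind, mdf_rows) else NULL
  prs <- if (length(prs_rows)) do.call(rbind, prs_rows) else NULL
  results <- NULL
  if (!is.null(prs)) {
    results <- compare_all_regions(prs[prs$condition == "pre", ],
                                   prs[prs$condition == "post", ],
                                   alpha = alpha)
  }
  if (!is.null(mdf)) {
    mres <- compare_all_muscles(mdf[mdf$condition == "pre", ],
                                mdf[mdf$condition == "post", ],
                                alpha = alpha)
    results <- if (is.null(results)) mres else rbind(results, mres)
  }
  rownames(results) <- NULL
  list(results = results, mdf = mdf, pressure = prs,
       n_recordings = length(recordings))
}

# Cohort directory layout: subject_<id>/<pre|post>/trial_<k>_<modality>.csv
# plus manifest.csv at the root.

#' Write a cohort to a directory tree
#'
#' Writes one CSV per recording under
#' `subject_<id>/<condition>/trial_<k>_<emg|pressure>.csv` and a
#' `manifest.csv` listing every file with its rate and the generating
#' seed.
#'
#' @param cohort List of `recording`s, typically from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Path to the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- attr(cohort, "config")
  seed <- if (!is.null(cfg)) cfg$seed else NA_integer_
  rows <- lapply(cohort, function(rec) {
    modality <- if (all(startsWith(names(rec$signals), "emg")))
      "emg" else "pressure"
    rel <- file.path(
      paste0("subject_", rec$subject_id), rec$condition,
      sprintf("trial_%d_%s.csv", rec$trial_index, modality))
    dest <- file.path(dir, rel)
    dir.create(dirname(dest), showWarnings = FALSE, recursive = TRUE)
    write_recording(rec, dest)
    data.frame(subject_id = rec$subject_id, condition = rec$condition,
               trial_index = rec$trial_index, modality = modality,
               rate_hz = rec$rate_hz, path = rel, seed = seed,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Malformed recordings are logged to stderr and skipped; it is an error
#' if nothing valid remains.
#'
#' @param dir Cohort directory containing `manifest.csv`.
#' @return A list of `recording` objects.
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) {
    stop("no manifest.csv in ", dir, call. = FALSE)
  }
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    rec <- tryCatch(
      read_recording(file.path(dir, row$path), rate_hz = row$rate_hz,
                     condition = row$condition, subject_id = row$subject_id,
                     trial_index = row$trial_index),
      error = function(e) {
        message("skipping malformed recording ", row$path, ": ",
                conditionMessage(e))
        NULL
      })
    if (!is.null(rec)) out[[length(out) + 1L]] <- rec
  }
  if (length(out) == 0L) {
    stop("all recordings in ", dir, " were malformed", call. = FALSE)
  }
  out
}

# Pipeline config file (JSON): top-level keys `cohort_dir`, `results_path`,
# `seed`, optional `synthetic` (synthetic_config overrides) and `analysis`
# (alpha, filter band, spectrum method, step detection).
read_pipeline_config <- function(config_path) {
  if (!file.exists(config_path)) {
    stop("config file not found: ", config_path, call. = FALSE)
  }
  cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  cfg$cohort_dir <- cfg$cohort_dir %||% "cohort"
  cfg$results_path <- cfg$results_path %||% "results.csv"
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$analysis <- utils::modifyList(
    list(alpha = 0.05, low_hz = 20, high_hz = 500,
         spectrum_method = "welch", threshold_frac = 0.2,
         min_separation_s = 0.4),
    as.list(cfg$analysis %||% list()))
  if (!(cfg$analysis$alpha > 0 && cfg$analysis$alpha < 1)) {
    stop("config error: alpha must be in (0, 1)", call. = FALSE)
  }
  syn <- as.list(cfg$synthetic %||% list())
  if (!is.null(syn$emg_band_pre)) {
    syn$emg_band_pre <- lapply(syn$emg_band_pre, as.numeric)
  }
  for (nm in c("mdf_shift_hz", "region_mean_peaks_gf", "fatigue_factors",
               "rpe_mean", "rpe_sd")) {
    if (!is.null(syn[[nm]])) syn[[nm]] <- unlist(syn[[nm]])
  }
  syn$seed <- cfg$seed
  cfg$synthetic_config <- do.call(synthetic_config, syn)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a synthetic cohort to disk
#'
#' Reads the pipeline config, generates the cohort and writes it (with a
#' manifest) under the configured `cohort_dir`.
#'
#' @param config_path Path to the JSON pipeline config.
#' @param base_dir Directory that relative paths in the config are
#'   resolved against (default: the config file's directory).
#' @return Integer exit status, invisibly (0 = success).
#' @export
cmd_simulate <- function(config_path, base_dir = dirname(config_path)) {
  status <- tryCatch({
    cfg <- read_pipeline_config(config_path)
    cohort <- generate_cohort(cfg$synthetic_config)
    dest <- resolve_path(cfg$cohort_dir, base_dir)
    mpath <- write_cohort(cohort, dest)
    message(sprintf("simulate: wrote %d recordings (%d trials) to %s",
                    length(cohort), length(cohort) / 2L, dest))
    0L
  }, error = function(e) {
    message("simulate failed: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

#' Analyze a cohort directory and write the results CSV
#'
#' @inheritParams cmd_simulate
#' @return Integer exit status, invisibly (0 = success).
#' @export
cmd_analyze <- function(config_path, base_dir = dirname(config_path)) {
  status <- tryCatch({
    cfg <- read_pipeline_config(config_path)
    cohort <- read_cohort(resolve_path(cfg$cohort_dir, base_dir))
    a <- cfg$analysis
    res <- analyze_cohort(cohort, alpha = a$alpha, low_hz = a$low_hz,
                          high_hz = a$high_hz,
                          spectrum_method = a$spectrum_method,
                          threshold_frac = a$threshold_frac,
                          min_separation_s = a$min_separation_s)
    rpath <- resolve_path(cfg$results_path, base_dir)
    write_results(res$results, rpath)
    message(sprintf("analyze: %d recordings -> %d comparisons in %s",
                    res$n_recordings, nrow(res$results), rpath))
    0L
  }, error = function(e) {
    message("analyze failed: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

#' Render a plain-text report from a results CSV
#'
#' One line per comparison in the style
#' `pre mean (SD) -> post mean (SD), decreased/increased by x%, P = ...`.
#'
#' @param results_path Path to a results CSV from [write_results()].
#' @param file Connection or path for the report text (default stdout).
#' @return Integer exit status, invisibly (0 = success).
#' @export
cmd_report <- function(results_path, file = stdout()) {
  status <- tryCatch({
    df <- read_results(results_path)
    lines <- vapply(seq_len(nrow(df)), function(i) {
      r <- df[i, ]
      dir_word <- if (r$percent_change < 0) "decreased" else "increased"
      sprintf(
        "%-10s %8.1f (%.1f) -> %8.1f (%.1f)  %s by %.1f%%  t(%d) = %+.2f, P = %.3f%s",
        r$label, r$pre_mean, r$pre_sd, r$post_mean, r$post_sd,
        dir_word, abs(r$percent_change), r$df, r$t_stat, r$p_value,
        if (isTRUE(r$significant) || identical(r$significant, "TRUE"))
          " *" else "")
    }, character(1))
    writeLines(lines, con = file)
    0L
  }, error = function(e) {
    message("report failed: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

resolve_path <- function(path, base_dir) {
  if (grepl("^(/|[A-Za-z]:)", path)) path else file.path(base_dir, path)
}

#' Command-line entry point
#'
#' Dispatches `simulate <config>`, `analyze <config>` or
#' `report <results.csv>`. Installed as `inst/cli/gaitfatigue.R`, runnable
#' with `Rscript`.
#'
#' @param args Character vector of command-line arguments (default: the
#'   process's trailing arguments).
#' @return Integer exit status, invisibly.
#' @export
gaitfatigue_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: gaitfatigue.R <simulate|analyze|report> <config.json | results.csv>"
  if (length(args) < 2L) {
    message(usage)
    return(invisible(2L))
  }
  cmd <- args[1]
  status <- switch(cmd,
    simulate = cmd_simulate(args[2]),
    analyze = cmd_analyze(args[2]),
    report = cmd_report(args[2]),
    {
      message("unknown command '", cmd, "'\n", usage)
      2L
    })
  invisible(status)
}
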