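# CSV exchange format: comma-separated, period decimal, UTF-8, one header
# row; first column is time in seconds, remaining columns are channels.

#' Read a multi-channel recording from CSV
#'
#' The file must have a header row, a first column of time stamps in
#' seconds, and one numeric column per channel. The time column is checked
#' for uniform spacing consistent with `rate_hz` (1% tolerance).
#'
#' @param path Path to a CSV file.
#' @param rate_hz Expected sampling rate in Hz.
#' @param condition `"pre"` or `"post"`.
#' @param subject_id,trial_index Recording metadata (defaults parsed from
#'   nothing; supply explicitly when reading cohort trees).
#' @return A [recording()].
#' @export
read_recording <- function(path, rate_hz, condition = c("pre", "post"),
                           subject_id = "S01", trial_index = 1L) {
  condition <- match.arg(condition)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (length(header) < 2L) {
    stop("format error: expected a header row with a time column and at ",
         "least one channel column in ", path, call. = FALSE)
  }
  if (suppressWarnings(!is.na(as.numeric(header[1])))) {
    stop("format error: first row of ", path,
         " is numeric; a header row is required", call. = FALSE)
  }
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(col)))))[1]
      stop(sprintf("parse error: non-numeric value in column '%s', row %d of %s",
                   names(df)[j], bad, path), call. = FALSE)
    }
  }
  tm <- df[[1]]
  if (nrow(df) >= 2L) {
    dt <- diff(tm)
    expect_dt <- 1 / rate_hz
    if (any(abs(dt - expect_dt) > 0.01 * expect_dt)) {
      stop(sprintf(
        "sampling error: time step in %s (median %.6g s) inconsistent with declared rate %g Hz",
        path, stats::median(dt), rate_hz), call. = FALSE)
    }
  }
  sigs <- lapply(names(df)[-1], function(nm) {
    sampled_signal(df[[nm]], rate_hz = rate_hz, label = nm)
  })
  names(sigs) <- names(df)[-1]
  recording(sigs, condition = condition, subject_id = subject_id,
            trial_index = trial_index)
}

#' Write a recording to CSV
#'
#' Inverse of [read_recording()]: time in seconds in the first column
#' (starting at 0), one column per channel, 6 decimal places.
#'
#' @param rec A [recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  n <- length(rec$signals[[1]]$samples)
  df <- data.frame(time_s = (seq_len(n) - 1L) / rec$rate_hz)
  for (nm in names(rec$signals)) df[[nm]] <- rec$signals[[nm]]$samples
  # fixed precision keeps files diffable and the round trip exact to 6 dp
  num <- vapply(df, function(col) sprintf("%.6f", col),
                character(nrow(df)))
  lines <- c(paste(names(df), collapse = ","),
             apply(matrix(num, nrow = nrow(df)), 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Write paired-comparison results to CSV
#'
#' One row per comparison: label, pre/post means and SDs, percent change,
#' t statistic, degrees of freedom, p value and significance flag.
#'
#' @param comparisons A data frame of paired comparisons, as returned by
#'   [compare_all_regions()] or [rbind()]-ed [paired_t_test()] rows.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(comparisons, path) {
  if (is.null(comparisons) || nrow(comparisons) == 0L) {
    stop("no comparisons to write; refusing to create an empty results file",
         call. = FALSE)
  }
  needed <- c("label", "pre_mean", "post_mean", "pre_sd", "post_sd",
              "percent_change", "t_stat", "df", "p_value", "significant")
  missing <- setdiff(needed, names(comparisons))
  if (length(missing)) {
    stop("results are missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(comparisons[, needed], path, row.names = FALSE)
  invisible(path)
}

#' Read a results CSV written by [write_results()]
#' @param path Path to the results file.
#' @return Data frame of comparisons.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("results file is empty: ", path, call. = FALSE)
  df
}
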