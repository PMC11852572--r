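# Readers and writers for the external formats the pipeline exchanges:
# Empatica-E4-style EDA CSV, ECG CSV / minimal WFDB, R-R interval CSV,
# session schedules, reaction-time (performance) tables, temperature traces
# and the feature table that links the signal and evaluation stages.
#
# All internal times are seconds relative to the recording start; epoch
# start times live only in the file headers.

# ---- domain type constructors -----------------------------------------------

#' EDA recording container
#'
#' A uniformly sampled skin-conductance series in microsiemens.
#'
#' @param samples numeric vector of skin conductance (µS); must be finite
#'   and non-negative.
#' @param fs sampling rate in Hz (nominally 4 for a wrist device).
#' @param start_time recording start, epoch seconds.
#' @return an object of class `eda_recording` with fields `samples`, `fs`,
#'   `start_time`.
#' @examples
#' r <- eda_recording(rep(6, 240), fs = 4)
#' duration_s(r)
#' @export
eda_recording <- function(samples, fs = 4, start_time = 0) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop_coldperf("`fs` must be a single positive number", "coldperf_validation_error")
  }
  if (any(!is.finite(samples))) {
    stop_coldperf("EDA samples must be finite (no NaN/NA/Inf)", "coldperf_validation_error")
  }
  if (any(samples < 0)) {
    stop_coldperf("skin conductance cannot be negative", "coldperf_validation_error")
  }
  structure(list(samples = samples, fs = fs, start_time = start_time),
            class = "eda_recording")
}

#' ECG recording container
#'
#' @param samples numeric vector in millivolts.
#' @param fs sampling rate in Hz (nominally 256).
#' @param start_time recording start, epoch seconds.
#' @return an object of class `ecg_recording`.
#' @export
ecg_recording <- function(samples, fs = 256, start_time = 0) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop_coldperf("`fs` must be a single positive number", "coldperf_validation_error")
  }
  if (any(!is.finite(samples))) {
    stop_coldperf("ECG samples must be finite (no NaN/NA/Inf)", "coldperf_validation_error")
  }
  structure(list(samples = samples, fs = fs, start_time = start_time),
            class = "ecg_recording")
}

#' R-R interval series container
#'
#' `beat_times[i]` is the time (s) of the beat that *terminates*
#' `intervals[i]` (ms). `valid` marks intervals accepted by cleaning;
#' `interpolated` marks intervals replaced by interpolation.
#'
#' @param beat_times strictly increasing beat times in seconds.
#' @param intervals positive R-R intervals in milliseconds.
#' @param valid,interpolated logical flags per interval.
#' @return an object of class `rr_series`.
#' @export
rr_series <- function(beat_times, intervals,
                      valid = rep(TRUE, length(intervals)),
                      interpolated = rep(FALSE, length(intervals))) {
  beat_times <- as.numeric(beat_times)
  intervals <- as.numeric(intervals)
  if (length(beat_times) != length(intervals)) {
    stop_coldperf("beat_times and intervals must have equal length",
                  "coldperf_validation_error")
  }
  if (any(!is.finite(intervals)) || any(intervals <= 0)) {
    stop_coldperf("R-R intervals must be finite and positive",
                  "coldperf_validation_error")
  }
  if (length(beat_times) > 1L && any(diff(beat_times) <= 0)) {
    stop_coldperf("beat times must be strictly increasing",
                  "coldperf_validation_error")
  }
  structure(list(beat_times = beat_times, intervals = intervals,
                 valid = as.logical(valid),
                 interpolated = as.logical(interpolated)),
            class = "rr_series")
}

#' Recording duration in seconds
#' @param x an `eda_recording` or `ecg_recording`.
#' @return duration in seconds (`length(samples) / fs`).
#' @export
duration_s <- function(x) length(x$samples) / x$fs

#' @export
print.eda_recording <- function(x, ...) {
  cat(sprintf("<eda_recording> %d samples @ %g Hz (%.1f s), range %.3f-%.3f uS\n",
              length(x$samples), x$fs, duration_s(x),
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf("<ecg_recording> %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$fs, duration_s(x)))
  invisible(x)
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d intervals, mean %.1f ms (%d interpolated)\n",
              length(x$intervals), mean(x$intervals), sum(x$interpolated)))
  invisible(x)
}

# ---- feature schema ---------------------------------------------------------

#' Names of the extracted physiological features
#'
#' Eight EDA features (means and standard deviations of the phasic
#' component, tonic component and time-varying sympathetic index, plus
#' skin-conductance-response counts at the 0.05 and 0.01 µS thresholds)
#' and three HRV features (high-frequency power, heart rate, RMSSD).
#'
#' @param set one of `"EDA"`, `"HRV"`, `"Both"`.
#' @return character vector of feature column names.
#' @export
feature_names <- function(set = c("Both", "EDA", "HRV")) {
  set <- match.arg(set)
  eda <- c("pheda_mean", "pheda_sd", "toneda_mean", "toneda_sd",
           "tvsymp_mean", "tvsymp_sd", "nsscr_005", "nsscr_001")
  hrv <- c("hf", "hr", "rmssd")
  switch(set, EDA = eda, HRV = hrv, Both = c(eda, hrv))
}

feature_table_columns <- function() {
  c("subject", "condition", "session", "task", feature_names("Both"), "label")
}

# ---- E4-style EDA CSV -------------------------------------------------------

#' Read an Empatica-E4-style EDA CSV
#'
#' Dialect: line 1 is the start time (epoch seconds), line 2 the sampling
#' rate (Hz), one skin-conductance sample (µS) per line afterwards.
#'
#' @param path file path.
#' @return an [eda_recording()].
#' @export
read_e4_eda <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) {
    stop_coldperf(sprintf("'%s': expected >= 3 lines (start, fs, samples)", path),
                  "coldperf_format_error")
  }
  start_time <- suppressWarnings(as.numeric(lines[1L]))
  fs <- suppressWarnings(as.numeric(lines[2L]))
  if (is.na(start_time)) {
    stop_coldperf(sprintf("'%s': line 1 ('%s') is not a numeric start time",
                          path, lines[1L]), "coldperf_format_error")
  }
  if (is.na(fs) || fs <= 0) {
    stop_coldperf(sprintf("'%s': line 2 ('%s') is not a positive sampling rate",
                          path, lines[2L]), "coldperf_format_error")
  }
  samples <- suppressWarnings(as.numeric(lines[-(1:2)]))
  if (any(is.na(samples))) {
    bad <- which(is.na(samples))[1L] + 2L
    stop_coldperf(sprintf("'%s': line %d is not a numeric sample", path, bad),
                  "coldperf_format_error")
  }
  eda_recording(samples, fs = fs, start_time = start_time)
}

#' Write an EDA recording in the E4 CSV dialect
#' @param rec an [eda_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_e4_eda <- function(rec, path) {
  stopifnot(inherits(rec, "eda_recording"))
  writeLines(c(sprintf("%.6f", rec$start_time),
               sprintf("%g", rec$fs),
               sprintf("%.10g", rec$samples)), path)
  invisible(path)
}

# ---- generic CSV helpers ----------------------------------------------------

read_checked_csv <- function(path, expected_cols) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(expected_cols, names(df))
  if (length(missing) > 0L) {
    stop_coldperf(sprintf(
      "'%s': missing column(s) %s; expected {%s}, found {%s}",
      path, paste(missing, collapse = ", "),
      paste(expected_cols, collapse = ", "),
      paste(names(df), collapse = ", ")), "coldperf_schema_error")
  }
  num <- vapply(df, is.numeric, logical(1L))
  if (any(vapply(df[num], function(x) any(is.na(x) | is.nan(x)), logical(1L)))) {
    stop_coldperf(sprintf("'%s': NaN/NA values are not accepted", path),
                  "coldperf_validation_error")
  }
  df
}

# ---- ECG --------------------------------------------------------------------

#' Read an ECG recording from CSV or a minimal WFDB record
#'
#' The CSV dialect has two columns `t` (seconds) and `mv`; sampling rate is
#' inferred from the time column. The WFDB branch reads a single- or
#' multi-channel format-16 record (`.hea` header plus `.dat` int16 samples)
#' and returns the first channel, applying gain and baseline.
#'
#' @param path CSV path, or WFDB record path/name (with or without `.hea`).
#' @param format `"csv"` or `"wfdb"`.
#' @param channel WFDB channel to extract (default 1).
#' @return an [ecg_recording()].
#' @export
read_ecg <- function(path, format = c("csv", "wfdb"), channel = 1L) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- read_checked_csv(path, c("t", "mv"))
    if (nrow(df) < 2L) stop_coldperf(sprintf("'%s': need >= 2 samples", path),
                                     "coldperf_format_error")
    dt <- diff(df$t)
    if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * stats::median(dt) + 1e-9) {
      stop_coldperf(sprintf("'%s': time column must be uniformly increasing", path),
                    "coldperf_format_error")
    }
    return(ecg_recording(df$mv, fs = 1 / stats::median(dt), start_time = df$t[1L]))
  }
  read_wfdb_ecg(path, channel = channel)
}

read_wfdb_ecg <- function(record, channel = 1L) {
  hea <- if (grepl("\\.hea$", record)) record else paste0(record, ".hea")
  if (!file.exists(hea)) {
    stop_coldperf(sprintf("WFDB header '%s' not found", hea), "coldperf_format_error")
  }
  lines <- readLines(hea)
  lines <- lines[!grepl("^#", lines)]
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(hdr) < 3L) {
    stop_coldperf(sprintf("'%s': malformed WFDB record line '%s'", hea, lines[1L]),
                  "coldperf_format_error")
  }
  n_sig <- as.integer(hdr[2L])
  fs <- as.numeric(hdr[3L])
  n_samp <- if (length(hdr) >= 4L) as.integer(hdr[4L]) else NA_integer_
  if (channel > n_sig) {
    stop_coldperf(sprintf("'%s': channel %d requested but record has %d signal(s)",
                          hea, channel, n_sig), "coldperf_format_error")
  }
  sig <- strsplit(trimws(lines[1L + channel]), "\\s+")[[1L]]
  dat_file <- file.path(dirname(hea), sig[1L])
  fmt <- sig[2L]
  if (!identical(sub("[x:+].*$", "", fmt), "16")) {
    stop_coldperf(sprintf("'%s': only WFDB format 16 is supported (got '%s')",
                          hea, fmt), "coldperf_format_error")
  }
  gain <- if (length(sig) >= 3L) as.numeric(sub("[(/].*$", "", sig[3L])) else 200
  if (!is.finite(gain) || gain == 0) gain <- 200
  baseline <- 0
  if (length(sig) >= 3L && grepl("\\(", sig[3L])) {
    baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", sig[3L]))
  }
  con <- file(dat_file, "rb")
  on.exit(close(con))
  raw_n <- file.info(dat_file)$size / 2L
  vals <- readBin(con, integer(), n = raw_n, size = 2L, signed = TRUE,
                  endian = "little")
  mat <- matrix(vals, nrow = n_sig)
  x <- (mat[channel, ] - baseline) / gain
  if (!is.na(n_samp) && ncol(mat) != n_samp) {
    stop_coldperf(sprintf("'%s': header promises %d samples, data has %d",
                          hea, n_samp, ncol(mat)), "coldperf_format_error")
  }
  # header gives the signal in physical units per ADC unit via gain (adu/mV)
  ecg_recording(x, fs = fs, start_time = 0)
}

#' Write an ECG recording as CSV (`t`, `mv`)
#' @param rec an [ecg_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(rec, path) {
  stopifnot(inherits(rec, "ecg_recording"))
  t <- rec$start_time + (seq_along(rec$samples) - 1L) / rec$fs
  utils::write.csv(data.frame(t = t, mv = rec$samples), path, row.names = FALSE)
  invisible(path)
}

#' Write a minimal WFDB format-16 record
#'
#' Intended for round-trip testing against [read_ecg()]; writes `.hea` and
#' `.dat` with a fixed gain.
#'
#' @param rec an [ecg_recording()].
#' @param record record path without extension.
#' @param gain ADC units per millivolt.
#' @return the record path, invisibly.
#' @export
write_wfdb_ecg <- function(rec, record, gain = 1000) {
  stopifnot(inherits(rec, "ecg_recording"))
  dat_name <- paste0(basename(record), ".dat")
  n <- length(rec$samples)
  writeLines(c(
    sprintf("%s 1 %s %d", basename(record), format(rec$fs), n),
    sprintf("%s 16 %g(0)/mV 16 0 0 0 0 ECG", dat_name, gain)
  ), paste0(record, ".hea"))
  con <- file(file.path(dirname(record), dat_name), "wb")
  on.exit(close(con))
  writeBin(as.integer(round(rec$samples * gain)), con, size = 2L,
           endian = "little")
  invisible(record)
}

# ---- RR CSV -----------------------------------------------------------------

#' Read an R-R interval CSV (`t_beat_s`, `rr_ms`)
#' @param path file path.
#' @return an [rr_series()].
#' @export
read_rr <- function(path) {
  df <- read_checked_csv(path, c("t_beat_s", "rr_ms"))
  rr_series(df$t_beat_s, df$rr_ms)
}

#' Write an R-R interval CSV
#' @param rr an [rr_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rr <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  utils::write.csv(data.frame(t_beat_s = rr$beat_times, rr_ms = rr$intervals),
                   path, row.names = FALSE)
  invisible(path)
}

# ---- schedules and performance ---------------------------------------------

valid_tasks <- function() c("CDS", "PRO", "GNG", "SPD", "SRT")
valid_conditions <- function() c("normal", "cold")

validate_schedule <- function(df, path = "<schedule>") {
  if (any(!df$condition %in% valid_conditions())) {
    stop_coldperf(sprintf("%s: condition must be one of {%s}", path,
                          paste(valid_conditions(), collapse = ", ")),
                  "coldperf_validation_error")
  }
  if (any(!df$task %in% valid_tasks())) {
    stop_coldperf(sprintf("%s: unknown task label(s): %s", path,
                          paste(unique(setdiff(df$task, valid_tasks())),
                                collapse = ", ")),
                  "coldperf_validation_error")
  }
  bad <- df$task_end_s <= df$task_start_s
  if (any(bad)) {
    i <- which(bad)[1L]
    stop_coldperf(sprintf(
      "%s: task_end_s <= task_start_s for subject %s %s session %s task %s",
      path, df$subject[i], df$condition[i], df$session[i], df$task[i]),
      "coldperf_validation_error")
  }
  invisible(df)
}

#' Read a session schedule CSV
#'
#' Columns: `subject`, `condition` (normal|cold), `session` (1-5), `task`
#' (CDS|PRO|GNG|SPD|SRT), `task_start_s`, `task_end_s` (seconds relative to
#' the recording start).
#'
#' @param path file path.
#' @return a data.frame of session records.
#' @export
read_schedule <- function(path) {
  df <- read_checked_csv(path, c("subject", "condition", "session", "task",
                                 "task_start_s", "task_end_s"))
  validate_schedule(df, path)
}

#' Write a session schedule CSV
#' @param schedule data.frame as returned by [read_schedule()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  validate_schedule(schedule)
  utils::write.csv(schedule, path, row.names = FALSE)
  invisible(path)
}

#' Read a reaction-time performance CSV
#'
#' Columns: `subject`, `condition`, `session`, `task`, `rt_ms` — one row
#' per subject x condition x session x task with the session's summary
#' reaction time (mean of correct trials) in milliseconds.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_performance <- function(path) {
  df <- read_checked_csv(path, c("subject", "condition", "session", "task", "rt_ms"))
  if (any(df$rt_ms <= 0)) {
    stop_coldperf(sprintf("'%s': reaction times must be positive", path),
                  "coldperf_validation_error")
  }
  df
}

#' Write a reaction-time performance CSV
#' @param perf data.frame with columns as in [read_performance()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_performance <- function(perf, path) {
  utils::write.csv(perf, path, row.names = FALSE)
  invisible(path)
}

# ---- temperature traces -----------------------------------------------------

#' Read a temperature CSV (`time_s`, `t_forehead`, `t_hand`, `t_calf`, `t_core`)
#' @param path file path.
#' @return data.frame; values outside the 20-45 degC plausibility band
#'   trigger a warning.
#' @export
read_temperature <- function(path) {
  df <- read_checked_csv(path, c("time_s", "t_forehead", "t_hand", "t_calf",
                                 "t_core"))
  temps <- unlist(df[c("t_forehead", "t_hand", "t_calf", "t_core")])
  if (any(temps < 20 | temps > 45)) {
    warning("temperature values outside the 20-45 degC plausibility band")
  }
  df
}

#' Write a temperature CSV
#' @param temps data.frame with columns as in [read_temperature()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_temperature <- function(temps, path) {
  utils::write.csv(temps, path, row.names = FALSE)
  invisible(path)
}

# ---- feature table ----------------------------------------------------------

#' Read the per-segment feature table
#'
#' Columns are exactly `subject`, `condition`, `session`, `task`, the 11
#' feature names of [feature_names()], and `label`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_feature_table <- function(path) {
  read_checked_csv(path, feature_table_columns())
}

#' Write the per-segment feature table
#' @param rows data.frame with the columns of [read_feature_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(rows, path) {
  missing <- setdiff(feature_table_columns(), names(rows))
  if (length(missing) > 0L) {
    stop_coldperf(sprintf("feature table missing column(s): %s",
                          paste(missing, collapse = ", ")),
                  "coldperf_schema_error")
  }
  utils::write.csv(rows[feature_table_columns()], path, row.names = FALSE)
  invisible(path)
}
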