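# R-peak detection, R-R interval cleaning and HRV features.

#' Detect R peaks in an ECG recording
#'
#' Band-pass (5-25 Hz Butterworth, zero-phase) + squared derivative +
#' moving-window integration + adaptive threshold with a 250 ms refractory
#' period; each detection is then refined to the local extremum of the
#' band-passed signal, which makes the detector insensitive to signal
#' polarity and amplitude scaling.
#'
#' @param ecg an [ecg_recording()] with fs >= 128 Hz and >= 10 s of signal.
#' @return numeric vector of strictly increasing peak times (s). An empty
#'   vector with a warning if no peaks are found.
#' @export
detect_r_peaks <- function(ecg) {
  stopifnot(inherits(ecg, "ecg_recording"))
  if (ecg$fs < 128) {
    stop_coldperf("R-peak detection requires fs >= 128 Hz",
                  "coldperf_validation_error")
  }
  if (duration_s(ecg) < 10) {
    stop_coldperf("R-peak detection requires >= 10 s of signal",
                  "coldperf_validation_error")
  }
  fs <- ecg$fs
  bp <- signal::butter(3, c(5, 25) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, ecg$samples)
  d <- c(0, diff(xf)) * fs
  e <- d^2
  w <- max(1L, round(0.15 * fs))
  integ <- stats::filter(e, rep(1 / w, w), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)
  refr <- round(0.25 * fs)
  thr <- 0.2 * stats::quantile(integ, 0.99)
  above <- integ > thr
  # candidate regions of consecutive supra-threshold samples
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- cbind(starts[runs$values], ends[runs$values])
  if (is.null(nrow(cand)) || nrow(cand) == 0L) {
    warning("no R peaks found")
    return(numeric(0))
  }
  peaks <- integer(0)
  half <- round(0.06 * fs)
  for (i in seq_len(nrow(cand))) {
    lo <- max(1L, cand[i, 1L] - half)
    hi <- min(length(xf), cand[i, 2L] + half)
    p <- lo - 1L + which.max(abs(xf[lo:hi]))
    if (length(peaks) == 0L || p - peaks[length(peaks)] > refr) {
      peaks <- c(peaks, p)
    } else if (abs(xf[p]) > abs(xf[peaks[length(peaks)]])) {
      peaks[length(peaks)] <- p
    }
  }
  if (length(peaks) == 0L) {
    warning("no R peaks found")
    return(numeric(0))
  }
  (peaks - 1L) / fs
}

#' Convert detected beat times to an R-R series
#' @param beat_times strictly increasing beat times, seconds.
#' @return an [rr_series()].
#' @export
beats_to_rr <- function(beat_times) {
  if (length(beat_times) < 2L) {
    stop_coldperf("need >= 2 beats to form intervals", "coldperf_validation_error")
  }
  rr_series(beat_times[-1L], diff(beat_times) * 1000)
}

#' Clean an R-R interval series
#'
#' Flags intervals outside \[`rr_min`, `rr_max`\] ms and ectopic intervals by
#' Malik's rule (an interval differing from the previous accepted interval
#' by more than 20%), then replaces flagged intervals by linear
#' interpolation between the nearest valid neighbours. Idempotent: a
#' second application changes nothing.
#'
#' @param rr an [rr_series()] with >= 3 intervals.
#' @param rr_min,rr_max physiological gate, ms (300 and 1500).
#' @param malik_tol relative-change tolerance of Malik's rule (0.2).
#' @return an [rr_series()] with `valid`/`interpolated` flags set and
#'   attribute `n_interpolated`.
#' @export
clean_rr <- function(rr, rr_min = 300, rr_max = 1500, malik_tol = 0.2) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$intervals
  n <- length(x)
  if (n < 3L) {
    stop_coldperf("cleaning requires >= 3 intervals", "coldperf_validation_error")
  }
  bad <- x < rr_min | x > rr_max
  # Malik's rule against the previous accepted interval
  last_ok <- NA_real_
  for (i in seq_len(n)) {
    if (bad[i]) next
    if (!is.na(last_ok) && abs(x[i] - last_ok) > malik_tol * last_ok) {
      bad[i] <- TRUE
    } else {
      last_ok <- x[i]
    }
  }
  if (sum(bad) > n / 2) {
    stop_coldperf(sprintf("%d of %d intervals invalid (> 50%%): segment unusable",
                          sum(bad), n), "coldperf_validation_error")
  }
  y <- x
  if (any(bad)) {
    ok <- which(!bad)
    y[bad] <- stats::approx(ok, x[ok], xout = which(bad), rule = 2)$y
  }
  out <- rr_series(rr$beat_times, y, valid = !bad,
                   interpolated = bad | rr$interpolated)
  attr(out, "n_interpolated") <- sum(bad)
  out
}

#' HRV features for one task-centered one-minute window
#'
#' From the cleaned intervals in the window: `hr = 60000 / mean(RR)` (bpm),
#' `rmssd` = root-mean-square of successive differences (ms), and `hf` =
#' absolute spectral power in 0.15-0.4 Hz (ms²) of the interval series,
#' estimated by cubic-interpolation resampling to 4 Hz, mean removal, and a
#' single Hann-windowed periodogram over the window.
#'
#' @param rr an [rr_series()] (cleaned or raw; cleaning is applied if any
#'   interval violates the gates).
#' @param midpoint window center, seconds; `NULL` uses the whole series.
#' @param width window width, seconds (default 60).
#' @param min_beats minimum number of beats required in the window.
#' @param task optional task name for error messages.
#' @return one-row data.frame with columns `hf`, `hr`, `rmssd`.
#' @export
hrv_feature_vector <- function(rr, midpoint = NULL, width = 60,
                               min_beats = 30, task = NULL) {
  stopifnot(inherits(rr, "rr_series"))
  seg <- if (is.null(midpoint)) rr else
    extract_window(rr, midpoint, width, task = task)
  if (length(seg$intervals) < min_beats) {
    stop_coldperf(sprintf("window holds %d beats; >= %d required%s",
                          length(seg$intervals), min_beats,
                          if (is.null(task)) "" else sprintf(" (task %s)", task)),
                  "coldperf_validation_error")
  }
  if (any(seg$intervals < 300 | seg$intervals > 1500)) {
    seg <- clean_rr(seg)
  }
  x <- seg$intervals
  hr <- 60000 / mean(x)
  rmssd <- if (length(x) > 1L) sqrt(mean(diff(x)^2)) else 0
  # spectral estimate on the evenly resampled interval series
  fs_r <- 4
  t <- seg$beat_times
  tt <- seq(min(t), max(t), by = 1 / fs_r)
  hf <- if (length(tt) >= 64L && stats::sd(x) > 0) {
    xi <- stats::spline(t, x, xout = tt)$y
    band_power(xi, fs_r, 0.15, 0.4)
  } else 0
  data.frame(hf = hf, hr = hr, rmssd = rmssd)
}
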