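# Time-varying sympathetic index (TVSymp) and window-level EDA features.
#
# TVSymp reconstructs the EDA signal in the 0.08-0.24 Hz band using
# variable-frequency complex demodulation (VFCDM) and takes the
# instantaneous amplitude of the reconstruction via the Hilbert transform.
# VFCDM runs in two stages: a fixed-frequency complex-demodulation filter
# bank first localizes the signal energy around evenly spaced carriers;
# the dominant instantaneous frequency of each component then serves as a
# time-varying carrier for a second, refining demodulation pass.

# Zero-phase FFT low-pass with a raised-cosine transition centered on the
# half-bandwidth fw (gain 1 below 0.4 fw, 0.5 at fw, 0 above 1.6 fw).
# The transition is symmetric about fw, so the demodulation filter bank
# (carriers spaced 2 fw apart) tiles the spectrum with unit total gain;
# an in-band tone is reconstructed once, never double-counted by
# neighbouring components.
fft_lowpass <- function(z, fs, fw) {
  n <- length(z)
  f <- (seq_len(n) - 1L) / n * fs
  f <- pmin(f, fs - f)                  # two-sided |frequency|
  f_pass <- 0.4 * fw
  f_stop <- 1.6 * fw
  g <- ifelse(f <= f_pass, 1,
              ifelse(f >= f_stop, 0,
                     0.5 * (1 + cos(pi * (f - f_pass) / (f_stop - f_pass)))))
  stats::fft(stats::fft(z) * g, inverse = TRUE) / n
}

# Complex demodulation of x (sampled at fs) around carrier phase phi
# (radians, length of x): returns the low-passed complex baseband signal.
demodulate <- function(x, phi, fs, fw) {
  fft_lowpass(x * exp(-1i * phi), fs, fw)
}

#' Time-varying sympathetic index of an EDA recording
#'
#' The input window is resampled to `fs_out` (2 Hz), normalized to zero
#' mean and unit variance (TVSymp is therefore unitless and invariant to
#' the input's mean and scale), decomposed with VFCDM (first-stage
#' half-bandwidth `fw` = 0.03 Hz, `n_comp` = 8 components, zero-phase
#' raised-cosine low-pass filters that tile the spectrum with unit gain),
#' and the components whose carrier frequencies fall in `band` are summed
#' and enveloped with the Hilbert transform.
#'
#' @param eda an [eda_recording()] of at least 120 s (two cycles of the
#'   0.08 Hz band edge are required for the band to be resolved).
#' @param band frequency band to reconstruct, Hz.
#' @param fw first-stage half-bandwidth, Hz.
#' @param n_comp number of demodulation components.
#' @param fs_out internal processing rate, Hz.
#' @return a list of class `tvsymp_series` with `amplitude` (non-negative,
#'   unitless), `reconstructed`, `fs` and `band`.
#' @export
compute_tvsymp <- function(eda, band = c(0.08, 0.24), fw = 0.03,
                           n_comp = 8, fs_out = 2) {
  stopifnot(inherits(eda, "eda_recording"))
  if (duration_s(eda) < 2 / band[1]) {
    stop_coldperf(sprintf(
      "TVSymp requires >= %.0f s of signal (two cycles of %.2f Hz)",
      2 / band[1], band[1]), "coldperf_validation_error")
  }
  t_in <- (seq_along(eda$samples) - 1L) / eda$fs
  t_out <- seq(0, max(t_in), by = 1 / fs_out)
  x <- stats::approx(t_in, eda$samples, xout = t_out)$y
  n <- length(x)
  s <- stats::sd(x)
  if (s == 0) {
    return(structure(list(amplitude = numeric(n), reconstructed = numeric(n),
                          fs = fs_out, band = band),
                     class = "tvsymp_series"))
  }
  x <- (x - mean(x)) / s
  tt <- (seq_len(n) - 1L) / fs_out
  centers <- (2 * seq_len(n_comp) - 1) * fw
  in_band <- centers >= band[1] & centers <= band[2]
  recon <- numeric(n)
  for (k in which(in_band)) {
    f0 <- centers[k]
    # stage 1: fixed-carrier demodulation isolates the component's band
    phi1 <- 2 * pi * f0 * tt
    z1 <- demodulate(x, phi1, fs_out, fw)
    s_k <- 2 * Re(z1 * exp(1i * phi1))
    # instantaneous frequency of the component, smoothed and confined to
    # the component's band so neighbouring components stay disjoint
    finst <- f0 + c(0, diff(unwrap_phase(Arg(z1)))) * fs_out / (2 * pi)
    finst <- stats::filter(finst, rep(1 / 9, 9), sides = 2)
    finst[is.na(finst)] <- f0
    finst <- pmin(pmax(as.numeric(finst), f0 - fw), f0 + fw)
    # stage 2: re-demodulate the component along its refined carrier
    phi2 <- 2 * pi * cumsum(finst) / fs_out
    z2 <- demodulate(s_k, phi2, fs_out, fw)
    recon <- recon + 2 * Re(z2 * exp(1i * phi2))
  }
  structure(list(amplitude = Mod(analytic_signal(recon)),
                 reconstructed = recon, fs = fs_out, band = band),
            class = "tvsymp_series")
}

unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  c(p[1], p[1] + cumsum(dp))
}

#' @export
print.tvsymp_series <- function(x, ...) {
  cat(sprintf("<tvsymp_series> %d samples @ %g Hz, band %.2f-%.2f Hz, mean amp %.3f\n",
              length(x$amplitude), x$fs, x$band[1], x$band[2],
              mean(x$amplitude)))
  invisible(x)
}

# ---- windowing --------------------------------------------------------------

#' Extract a task-centered window from a series
#'
#' Half-open convention `[midpoint - width/2, midpoint + width/2)` at the
#' native sampling rate, so a 60 s window at 4 Hz is exactly 240 samples.
#'
#' @param x an [eda_recording()], [ecg_recording()], numeric vector (with
#'   `fs`), or [rr_series()].
#' @param midpoint window center, seconds from the series start.
#' @param width window width, seconds (default 60).
#' @param fs sampling rate; only needed for bare numeric vectors.
#' @param task optional task name used in error messages.
#' @return same class as the input, restricted to the window. For an
#'   `rr_series`, intervals whose terminating beat falls in the window are
#'   kept.
#' @export
extract_window <- function(x, midpoint, width = 60, fs = NULL, task = NULL) {
  lab <- if (is.null(task)) "" else sprintf(" (task %s)", task)
  lo <- midpoint - width / 2
  hi <- midpoint + width / 2
  if (inherits(x, "rr_series")) {
    keep <- x$beat_times >= lo & x$beat_times < hi
    if (lo < 0 || hi > max(x$beat_times)) {
      stop_coldperf(sprintf("window [%g, %g) exceeds the R-R series span%s",
                            lo, hi, lab), "coldperf_window_error")
    }
    return(rr_series(x$beat_times[keep], x$intervals[keep],
                     x$valid[keep], x$interpolated[keep]))
  }
  if (inherits(x, c("eda_recording", "ecg_recording"))) {
    fs <- x$fs
    v <- x$samples
  } else {
    if (is.null(fs)) stop("`fs` is required for a bare numeric series")
    v <- as.numeric(x)
  }
  i0 <- round(lo * fs)
  n_w <- round(width * fs)
  if (i0 < 0 || i0 + n_w > length(v)) {
    stop_coldperf(sprintf(
      "window [%g, %g) s exceeds the recording bounds [0, %g) s%s",
      lo, hi, length(v) / fs, lab), "coldperf_window_error")
  }
  seg <- v[(i0 + 1L):(i0 + n_w)]
  if (inherits(x, "eda_recording")) return(eda_recording(seg, fs, x$start_time + lo))
  if (inherits(x, "ecg_recording")) return(ecg_recording(seg, fs, x$start_time + lo))
  seg
}

# ---- SCR counting -----------------------------------------------------------

#' Count non-specific skin conductance responses in a phasic segment
#'
#' An SCR is a local maximum of the phasic component whose onset-to-peak
#' amplitude (peak minus the preceding local minimum) exceeds `threshold`,
#' with a minimum inter-peak separation of `min_sep` seconds (the larger
#' peak wins within a conflict).
#'
#' @param phasic numeric vector, the phasic EDA component (µS).
#' @param threshold amplitude threshold, µS (> 0); canonical values 0.05
#'   and 0.01.
#' @param fs sampling rate, Hz.
#' @param min_sep minimum peak separation, seconds.
#' @return integer count.
#' @export
count_nsscr <- function(phasic, threshold, fs = 4, min_sep = 1) {
  stopifnot(threshold > 0)
  x <- as.numeric(phasic)
  n <- length(x)
  if (n < 3L) return(0L)
  is_max <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n], FALSE)
  is_min <- c(TRUE, x[2:(n - 1)] <= x[1:(n - 2)] & x[2:(n - 1)] < x[3:n], FALSE)
  peaks <- which(is_max)
  if (length(peaks) == 0L) return(0L)
  mins <- which(is_min)
  amp <- vapply(peaks, function(p) {
    prev <- mins[mins < p]
    onset <- if (length(prev)) max(prev) else 1L
    x[p] - x[onset]
  }, numeric(1))
  # enforce the minimum separation, keeping the larger peak
  ord <- order(amp, decreasing = TRUE)
  kept <- logical(0)
  kept_pos <- integer(0)
  for (i in ord) {
    if (all(abs(peaks[i] - kept_pos) >= min_sep * fs)) {
      kept_pos <- c(kept_pos, peaks[i])
      kept <- c(kept, amp[i] > threshold)
    }
  }
  sum(kept)
}

# ---- feature vector ---------------------------------------------------------

#' EDA features for one task-centered one-minute window
#'
#' Decomposes a context window around the task midpoint (the window is
#' widened to `context` seconds so the decomposition and TVSymp see enough
#' signal, then clipped back), computes TVSymp, and summarizes the central
#' `width` seconds: means and SDs of the phasic component, tonic component
#' and TVSymp, plus SCR counts at the 0.05 and 0.01 µS thresholds.
#'
#' @param eda an [eda_recording()].
#' @param midpoint window center, seconds.
#' @param width analysis window, seconds (default 60).
#' @param context decomposition context on each side of the midpoint,
#'   seconds (default 60, giving a 120 s context window).
#' @param task optional task name for error messages.
#' @return one-row data.frame with columns `pheda_mean`, `pheda_sd`,
#'   `toneda_mean`, `toneda_sd`, `tvsymp_mean`, `tvsymp_sd`, `nsscr_005`,
#'   `nsscr_001`.
#' @export
eda_feature_vector <- function(eda, midpoint, width = 60, context = 60,
                               task = NULL) {
  stopifnot(inherits(eda, "eda_recording"))
  total <- duration_s(eda)
  lo <- midpoint - width / 2
  hi <- midpoint + width / 2
  if (lo < 0 || hi > total) {
    stop_coldperf(sprintf(
      "window [%g, %g) s exceeds the recording bounds [0, %g) s%s",
      lo, hi, total, if (is.null(task)) "" else sprintf(" (task %s)", task)),
      "coldperf_window_error")
  }
  # context window, shifted inside the recording if the edges clip it
  c_lo <- max(0, midpoint - context)
  c_hi <- min(total, midpoint + context)
  need <- 2 * context
  if (c_hi - c_lo < need) {
    if (c_lo == 0) c_hi <- min(total, need) else c_lo <- max(0, c_hi - need)
  }
  ctx <- extract_window(eda, (c_lo + c_hi) / 2, width = c_hi - c_lo)
  dec <- decompose_eda(ctx)
  tvs <- compute_tvsymp(ctx)
  off <- lo - c_lo
  ph <- extract_window(dec$phasic, off + width / 2, width, fs = eda$fs)
  tn <- extract_window(dec$tonic, off + width / 2, width, fs = eda$fs)
  tv <- extract_window(tvs$amplitude, off + width / 2, width, fs = tvs$fs)
  data.frame(
    pheda_mean = mean(ph), pheda_sd = stats::sd(ph),
    toneda_mean = mean(tn), toneda_sd = stats::sd(tn),
    tvsymp_mean = mean(tv), tvsymp_sd = stats::sd(tv),
    nsscr_005 = count_nsscr(ph, 0.05, fs = eda$fs),
    nsscr_001 = count_nsscr(ph, 0.01, fs = eda$fs))
}
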