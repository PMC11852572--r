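# Internal numerical helpers shared across modules.

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Returns the complex analytic signal `x + i * H(x)`; `Mod()` of the result
#' is the instantaneous-amplitude (envelope) series.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
#' @noRd
analytic_signal <- function(x) {
  n <- length(x)
  stopifnot(n > 1L, all(is.finite(x)))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# One-sided power spectral density with a Hann window.
# Scaled so that a sinusoid of amplitude a integrates to a^2/2 over its band.
# Returns list(freq, psd) with df = fs / length(x).
hann_psd <- function(x, fs) {
  n <- length(x)
  stopifnot(n > 8L)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))  # periodic Hann
  xw <- (x - mean(x)) * w
  X <- stats::fft(xw)
  nh <- floor(n / 2) + 1L
  u <- mean(w^2)
  psd <- (Mod(X[seq_len(nh)])^2) / (fs * n * u)
  psd[2:(nh - 1L)] <- 2 * psd[2:(nh - 1L)]
  list(freq = (seq_len(nh) - 1) * fs / n, psd = psd)
}

# Integrated spectral power of x (sampled at fs) within [f_lo, f_hi].
band_power <- function(x, fs, f_lo, f_hi) {
  sp <- hann_psd(x, fs)
  df <- fs / length(x)
  sum(sp$psd[sp$freq >= f_lo & sp$freq <= f_hi]) * df
}

# Derive a stream-specific 32-bit seed from a base seed so that independent
# stages never consume the same random numbers.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(lapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p)) else as.numeric(p)
  })))
  s <- 0
  for (p in parts) s <- (s * 69069 + (as.numeric(p) %% 2147483647)) %% 2147483647
  as.integer(s)
}

# Evaluate expr under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Stop with a classed condition so callers/tests can match on error type.
stop_coldperf <- function(msg, class) {
  stop(structure(
    class = c(class, "coldperf_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
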