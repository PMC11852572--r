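# Shared fixtures, built in code at test time.

# Feature-level two-cluster problem: n_sub subjects x n_seg segments with
# two informative dimensions separated by `sep` SDs. Labels are balanced
# Bernoulli draws, so subjects carry both classes.
make_separable_problem <- function(n_sub = 16, n_seg = 8, sep = 4,
                                   n_feat = 5, seed = 3) {
  set.seed(seed)
  n <- n_sub * n_seg
  g <- rep(sprintf("P%02d", seq_len(n_sub)), each = n_seg)
  y <- stats::rbinom(n, 1, 0.45)
  X <- matrix(stats::rnorm(n * n_feat), ncol = n_feat)
  X[, 1] <- X[, 1] + sep * y
  X[, 2] <- X[, 2] - sep * y
  colnames(X) <- paste0("f", seq_len(n_feat))
  list(X = X, y = y, groups = g)
}

# EDA recording with SCR events confined to the central minute of a 180 s
# recording, so the one-minute task window sees all of them.
make_scr_recording <- function(amplitudes, tonic = 5, noise_sd = 0,
                               seed = 1) {
  k <- length(amplitudes)
  times <- 90 + seq(-25, 25, length.out = k)
  generate_eda(tonic, drift_slope = 0.01,
               scr_events = data.frame(time_s = times, amplitude = amplitudes),
               duration = 180, fs = 4, noise_sd = noise_sd, seed = seed)
}

quiet_decompose <- function(...) suppressWarnings(decompose_eda(...))
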