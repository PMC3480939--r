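# Independent reference implementations used as oracles.  These are written
# as plain loops, deliberately sharing no code with the package internals.

# Direct time-domain circular convolution: y[n] = sum_k h[k] x[(n - k) mod N]
circ_conv <- function(x, h) {
  n <- length(x)
  y <- numeric(n)
  for (t in seq_len(n)) {
    acc <- 0
    for (k in seq_along(h)) {
      idx <- ((t - 1) - (k - 1)) %% n + 1
      acc <- acc + h[k] * x[idx]
    }
    y[t] <- acc
  }
  y
}

# Brute-force a trous decomposition: filters dilated by zero insertion, then
# circular convolution at every level.
atrous_direct <- function(x, levels = 5, wavelet = "coif3") {
  f <- wavelet_filters(wavelet)
  upsample <- function(h, j) {
    if (j == 1) return(h)
    out <- numeric((length(h) - 1) * 2^(j - 1) + 1)
    out[seq(1, length(out), by = 2^(j - 1))] <- h
    out
  }
  a <- x
  coeffs <- matrix(0, length(x), levels + 1)
  for (j in seq_len(levels)) {
    coeffs[, j] <- circ_conv(a, upsample(f$hi, j))
    a <- circ_conv(a, upsample(f$lo, j))
  }
  coeffs[, levels + 1] <- a
  coeffs
}

# Full-resolution periodogram power and the fraction inside a band (Hz).
band_fraction <- function(x, band, fs = 128) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  keep <- f <= fs / 2
  p <- p[keep]; f <- f[keep]
  sum(p[f >= band[1] & f <= band[2]]) / sum(p)
}

# Reference (slow) retained-power computation for the adaptive loop.
p_ring_direct <- function(a, T, kind, span, tau = 1) {
  sp <- shrink_coefficients(a, T, kind, lambda = 2 * T, tau = tau)
  mean(sp$a_ring[span]^2)
}

# Shared small fixtures (built once per test run).
ref_segments_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- sim_reference(n_segments = 40, seed = 7101)
    cache
  }
})
detection_model_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- calibrate_detection(ref_segments_fixture())
    cache
  }
})
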