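# Orthonormal wavelet filter tables.
#
# The Coiflet-3 scaling (low-pass) decomposition filter, 18 taps, in the
# standard orthonormal normalisation (sum h = sqrt(2), sum h^2 = 1).  The
# values are the canonical published table; they satisfy the orthonormality
# conditions sum_n h[n] h[n + 2k] = delta_k to ~1e-13, which bounds the
# reconstruction error of the transform built on them.
.coif3_dec_lo <- c(
  -3.459977283621256e-05, -7.098330313814125e-05,  4.662169601128863e-04,
   1.117518770890602e-03, -2.574517688750224e-03, -9.007976136661580e-03,
   1.588054486361590e-02,  3.455502757306163e-02, -8.230192710688598e-02,
  -7.179982161931202e-02,  4.284834763776188e-01,  7.937772226256206e-01,
   4.051769024096169e-01, -6.112339000267287e-02, -6.577191128185550e-02,
   2.345269614183627e-02,  7.782596427325418e-03, -3.793512864491014e-03)

#' Orthonormal analysis filter pair for a named wavelet
#'
#' Returns the low-pass (scaling) and high-pass (wavelet) decomposition
#' filters.  The high-pass filter is the quadrature mirror of the low-pass
#' one, `g[n] = (-1)^n h[L - 1 - n]` (0-based), so the pair is
#' power-complementary and the stationary wavelet transform built on it is
#' exactly invertible.
#'
#' @param wavelet Filter family name.  Only `"coif3"` (Coiflet with six
#'   vanishing wavelet moments, 18 taps) is shipped; it is the conventional
#'   choice for ocular-artefact work because the scaling function resembles
#'   an eye-blink deflection.
#' @return A list with numeric vectors `lo` and `hi`.
#' @examples
#' f <- wavelet_filters("coif3")
#' sum(f$lo) - sqrt(2)   # ~0
#' sum(f$lo^2) - 1       # ~0
#' @export
wavelet_filters <- function(wavelet = "coif3") {
  lo <- switch(wavelet,
    coif3 = .coif3_dec_lo,
    stop("unknown wavelet '", wavelet, "'; only 'coif3' is available"))
  n <- seq_along(lo) - 1L
  hi <- (-1)^n * rev(lo)
  list(lo = lo, hi = hi)
}
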