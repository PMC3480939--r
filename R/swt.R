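# Translation-invariant (stationary / a trous) wavelet transform.
#
# The transform operates on a right-extended copy of the input so that border
# discontinuities do not masquerade as artefactual coefficients, and uses
# circular convolution on the extended signal, under which the transform is
# exactly translation covariant and exactly invertible.

# Cache of dilated filter spectra, keyed by "wavelet/N".  Decomposing every
# 1-second segment of a session reuses the same N = 256 spectra thousands of
# times, so this is the hot path.
.swt_cache <- new.env(parent = emptyenv())

# Frequency responses of the level-j dilated filters (j = 1..levels) for a
# circular transform of length n.  The dilated filter places tap k at index
# (k * 2^(j-1)) mod n, accumulating wrapped taps.
.dilated_spectra <- function(wavelet, n, levels) {
  key <- paste(wavelet, n, levels, sep = "/")
  hit <- .swt_cache[[key]]
  if (!is.null(hit)) return(hit)
  f <- wavelet_filters(wavelet)
  out <- vector("list", levels)
  for (j in seq_len(levels)) {
    step <- 2L^(j - 1L)
    lo <- hi <- numeric(n)
    idx <- ((seq_along(f$lo) - 1L) * step) %% n + 1L
    for (k in seq_along(f$lo)) {
      lo[idx[k]] <- lo[idx[k]] + f$lo[k]
      hi[idx[k]] <- hi[idx[k]] + f$hi[k]
    }
    out[[j]] <- list(LO = stats::fft(lo), HI = stats::fft(hi))
  }
  .swt_cache[[key]] <- out
  out
}

#' Extend a signal on the right by mirror reflection
#'
#' Reflects the tail of the signal (whole-point reflection, i.e. the boundary
#' sample itself is not duplicated) until the requested length is reached, so
#' `c(1, 2, 3)` extended to length 5 becomes `c(1, 2, 3, 2, 1)`.  Extension
#' suppresses the spurious large coefficients a border discontinuity would
#' otherwise create in a circular transform.
#'
#' @param x Numeric vector (one EEG channel, microvolts).
#' @param target_len Desired output length, `>= length(x)`.
#' @return Numeric vector of length `target_len` whose first `length(x)`
#'   samples are `x`.
#' @export
extend_symmetric <- function(x, target_len) {
  n <- length(x)
  if (n < 1L) stop("signal must contain at least one sample")
  if (target_len < n) stop("target_len must be >= length(x)")
  if (target_len == n) return(x)
  if (n == 1L) return(rep(x, length.out = target_len))
  # reflect indices with period 2(n - 1): n+1 -> n-1, n+2 -> n-2, ...
  k <- seq_len(target_len) - 1L
  per <- k %% (2L * (n - 1L))
  idx <- ifelse(per < n, per, 2L * (n - 1L) - per) + 1L
  x[idx]
}

#' Five-level stationary wavelet decomposition of one channel
#'
#' Decomposes a signal with the undecimated (a trous) algorithm: at level j
#' the analysis filters are dilated by `2^(j-1)` and applied by circular
#' convolution, with no downsampling, so every coefficient sequence has the
#' full (extended) length.  The input is first extended on the right with
#' [extend_symmetric()] to the smallest multiple of `2^levels` that at least
#' doubles it (a 128-sample segment becomes 256 samples), covering the
#' support of the deepest dilated filter.
#'
#' At 128 Hz the levels map onto frequency bands
#' d1: 32–64, d2: 16–32, d3: 8–16, d4: 4–8, d5: 2–4 and a5: 0–2 Hz.
#'
#' @param x Numeric vector; with `extend = FALSE` its length must be a
#'   multiple of `2^levels`.
#' @param levels Decomposition depth (default 5).
#' @param wavelet Filter family, see [wavelet_filters()].
#' @param extend Extend the signal before transforming (default `TRUE`).
#' @return An object of class `"swt_decomposition"`: a list with `coeffs`
#'   (matrix, extended length x `levels + 1`, columns `d1..d<levels>` then
#'   `a<levels>`), `original_length`, `levels`, `wavelet`.
#' @seealso [swt_reconstruct()] for the exact inverse.
#' @export
swt_decompose <- function(x, levels = 5L, wavelet = "coif3", extend = TRUE) {
  if (!all(is.finite(x))) stop("signal contains non-finite samples")
  n0 <- length(x)
  block <- 2L^levels
  if (extend) {
    target <- block * ceiling(2L * n0 / block)
    x <- extend_symmetric(x, target)
  } else if (n0 %% block != 0L) {
    stop("length must be a multiple of 2^levels; extend the signal first ",
         "(see extend_symmetric)")
  }
  n <- length(x)
  spec <- .dilated_spectra(wavelet, n, levels)
  coeffs <- matrix(0, n, levels + 1L,
                   dimnames = list(NULL, c(paste0("d", seq_len(levels)),
                                           paste0("a", levels))))
  A <- stats::fft(x)
  for (j in seq_len(levels)) {
    coeffs[, j] <- Re(stats::fft(A * spec[[j]]$HI, inverse = TRUE)) / n
    A <- A * spec[[j]]$LO
  }
  coeffs[, levels + 1L] <- Re(stats::fft(A, inverse = TRUE)) / n
  structure(list(coeffs = coeffs, original_length = n0, levels = levels,
                 wavelet = wavelet),
            class = "swt_decomposition")
}

#' Inverse stationary wavelet transform
#'
#' Exact inverse of [swt_decompose()]: at each level the approximation is
#' recovered as `(conj(H) A + conj(G) D) / 2` in the frequency domain, which
#' is an identity for a power-complementary orthonormal filter pair.  The
#' result is truncated to the original (pre-extension) length.
#'
#' @param decomp An `"swt_decomposition"` object (its `coeffs` may have been
#'   modified, e.g. by a shrinkage rule).
#' @return Numeric vector of length `decomp$original_length`.
#' @export
swt_reconstruct <- function(decomp) {
  stopifnot(inherits(decomp, "swt_decomposition"))
  coeffs <- decomp$coeffs
  levels <- decomp$levels
  if (ncol(coeffs) != levels + 1L)
    stop("decomposition must hold levels + 1 coefficient sequences")
  n <- nrow(coeffs)
  spec <- .dilated_spectra(decomp$wavelet, n, levels)
  A <- stats::fft(coeffs[, levels + 1L])
  for (j in rev(seq_len(levels))) {
    D <- stats::fft(coeffs[, j])
    A <- (Conj(spec[[j]]$LO) * A + Conj(spec[[j]]$HI) * D) / 2
  }
  out <- Re(stats::fft(A, inverse = TRUE)) / n
  out[seq_len(decomp$original_length)]
}
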