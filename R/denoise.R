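# Artefact removal: adaptive SWT denoising and the fixed-threshold
# comparators.  All denoisers share the contract: a segment the detector
# declared clean is returned bit-identical; otherwise the wavelet
# coefficients are split into artefact and signal parts and the inverse
# transform of the signal part is returned.

# Rebuild a channel from a decomposition whose coefficient columns have been
# replaced by the retained (signal) parts.
.reconstruct_signal <- function(decomp, a_ring_mat) {
  decomp$coeffs <- a_ring_mat
  swt_reconstruct(decomp)
}

#' Adaptive stationary-wavelet denoising of one segment
#'
#' The package's core algorithm.  For every channel and every decomposition
#' level (d1..d5 and a5), the threshold is initialised at the universal
#' threshold of that level's coefficients, the coefficients are split into
#' artefact and signal parts with the chosen shrinkage function, and the
#' threshold is lowered geometrically (`T <- T - mu T`) until the power of
#' the retained part no longer exceeds the detection threshold `ThP[i, j]`
#' calibrated on resting reference EEG — see [adapt_level()].  The denoised
#' channel is the inverse transform of the retained coefficients.
#'
#' Segments the detector declared clean are returned unchanged: the
#' algorithm never operates on clean EEG.
#'
#' @param segment Channels x samples matrix (uV).
#' @param detection `"artefact_detection"` result for this segment; its
#'   cached decompositions are reused, not recomputed.
#' @param model The `"detection_model"` whose `ThP` drives the adaptation.
#' @param kind Shrinkage kind (default `"garrote"`, the best performer).
#' @param mu Learning rate; per-kind default from [default_mu()].
#' @param max_iter Per-level iteration cap (capped levels are recorded).
#' @return Denoised segment (same shape).  Attribute `"aswtd_log"` holds a
#'   data frame with the final threshold, iteration count and cap flag per
#'   channel and level.
#' @export
denoise_aswtd <- function(segment, detection, model, kind = "garrote",
                          mu = default_mu(kind), max_iter = 500L) {
  stopifnot(inherits(detection, "artefact_detection"))
  if (detection$clean) return(segment)
  decomps <- detection$features$decomps
  span <- seq_len(ncol(segment))
  out <- segment
  log <- vector("list", nrow(segment))
  for (j in seq_len(nrow(segment))) {
    dec <- decomps[[j]]
    ring <- dec$coeffs
    nl <- ncol(ring)
    Ts <- its <- numeric(nl); capped <- logical(nl)
    for (i in seq_len(nl)) {
      ad <- adapt_level(dec$coeffs[, i], ThP = model$ThP[i, j], kind = kind,
                        mu = mu, span = span, max_iter = max_iter)
      ring[, i] <- ad$split$a_ring
      Ts[i] <- ad$T; its[i] <- ad$iterations; capped[i] <- ad$capped
    }
    out[j, ] <- .reconstruct_signal(dec, ring)
    log[[j]] <- data.frame(channel = j, level = colnames(ring),
                           final_T = Ts, iterations = its, capped = capped)
  }
  attr(out, "aswtd_log") <- do.call(rbind, log)
  out
}

# Shared one-shot shrinkage driver: thresholds[i, j] applied with soft
# shrinkage to the selected levels of every channel.
.denoise_fixed <- function(segment, detection, thresholds,
                           levels_used = NULL, kind = "soft") {
  if (detection$clean) return(segment)
  decomps <- detection$features$decomps
  out <- segment
  for (j in seq_len(nrow(segment))) {
    dec <- decomps[[j]]
    ring <- dec$coeffs
    use <- if (is.null(levels_used)) seq_len(ncol(ring)) else levels_used
    for (i in use)
      ring[, i] <- shrink_coefficients(dec$coeffs[, i], thresholds[i, j],
                                       kind = kind)$a_ring
    out[j, ] <- .reconstruct_signal(dec, ring)
  }
  out
}

#' Fixed universal-threshold denoising (SWT-UNV)
#'
#' One-shot soft shrinkage of every level at its universal threshold — the
#' adaptive algorithm frozen at its starting point.  Known behaviour: the
#' universal threshold is usually larger than necessary, so artefacts are
#' under-removed (spectral distortion above 1 on ocular contamination).
#'
#' @inheritParams denoise_aswtd
#' @return Denoised segment.
#' @export
denoise_unv <- function(segment, detection, model = NULL) {
  if (detection$clean) return(segment)
  decomps <- detection$features$decomps
  span <- seq_len(ncol(segment))
  nl <- ncol(decomps[[1L]]$coeffs)
  thr <- vapply(decomps, function(d)
    apply(d$coeffs[span, , drop = FALSE], 2L, universal_threshold),
    numeric(nl))
  .denoise_fixed(segment, detection, thr)
}

#' Calibrate fixed reference-derived thresholds (SWT-REF)
#'
#' Per level and channel, the threshold is the maximum over the reference
#' segments of that level's universal threshold: a fixed, conservative cut
#' derived once from clean resting data.
#'
#' @param reference_segments List of resting 1-second segments.
#' @param levels,wavelet Decomposition settings.
#' @return `(levels + 1) x channels` threshold matrix.
#' @export
calibrate_ref_thresholds <- function(reference_segments, levels = 5L,
                                     wavelet = "coif3") {
  if (length(reference_segments) < 1L) stop("reference segments required")
  span <- seq_len(ncol(reference_segments[[1L]]))
  per_seg <- lapply(reference_segments, function(seg) {
    dec <- .decompose_segment(seg, levels, wavelet)
    vapply(dec, function(d)
      apply(d$coeffs[span, , drop = FALSE], 2L, universal_threshold),
      numeric(levels + 1L))
  })
  Reduce(pmax, per_seg)
}

#' Fixed reference-threshold denoising (SWT-REF)
#'
#' One-shot soft shrinkage at thresholds from [calibrate_ref_thresholds()].
#'
#' @inheritParams denoise_aswtd
#' @param ref_thresholds Matrix from [calibrate_ref_thresholds()].
#' @return Denoised segment.
#' @export
denoise_ref <- function(segment, detection, ref_thresholds) {
  if (is.null(ref_thresholds)) stop("SWT-REF requires reference thresholds")
  .denoise_fixed(segment, detection, ref_thresholds)
}

#' SURE-optimal soft threshold for one coefficient vector
#'
#' Minimises Stein's unbiased risk estimate
#' `SURE(T) = N - 2 #\{|y| <= T\} + sum(min(|y|, T)^2)` over the candidate
#' set `{|y_t|}`, where `y` is the coefficient vector normalised by its
#' MADN; the winning candidate is returned on the original scale.  Ties are
#' broken towards the smaller threshold; a zero-spread vector returns 0.
#'
#' @param a Coefficient vector, length >= 2.
#' @return Scalar threshold (same units as `a`).
#' @export
sure_threshold <- function(a) {
  if (length(a) < 2L) stop("SURE needs at least 2 coefficients")
  s <- madn(a)
  if (s == 0) return(0)
  y <- sort(abs(a / s))
  n <- length(y)
  k <- seq_len(n)                      # candidates T = y[k]; #{|y| <= T} = k
  csum <- cumsum(y^2)
  risk <- n - 2 * k + (csum + y^2 * (n - k))
  s * y[which.min(risk)]
}

#' SURE-threshold soft denoising (SWT-SURE)
#'
#' Soft shrinkage with a per-level, per-channel SURE-optimal threshold.
#' Following the ocular-removal literature, only the levels covering 0-16 Hz
#' (d3, d4, d5, a5) are thresholded when a purely low-frequency artefact was
#' detected; all levels are thresholded when a high-frequency (muscle)
#' artefact is present.  SURE thresholds tend to come out below the optimum,
#' so this baseline over-corrects (spectral distortion below 1, strongly so
#' for muscle artefacts).
#'
#' @inheritParams denoise_aswtd
#' @return Denoised segment.
#' @export
denoise_sure <- function(segment, detection, model = NULL) {
  if (detection$clean) return(segment)
  decomps <- detection$features$decomps
  span <- seq_len(ncol(segment))
  nl <- ncol(decomps[[1L]]$coeffs)
  levels_used <- if (detection$high_freq) seq_len(nl) else 3:nl
  thr <- vapply(decomps, function(d)
    apply(d$coeffs[span, , drop = FALSE], 2L, sure_threshold),
    numeric(nl))
  .denoise_fixed(segment, detection, thr, levels_used = levels_used)
}
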