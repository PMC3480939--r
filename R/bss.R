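# Blind-source-separation comparator: AMUSE decomposition plus automatic
# artefact-component identification.  AMUSE recovers sources by
# eigendecomposition of the symmetrised lag-1 covariance of pre-whitened
# data; the rejection criteria (amplitude, kurtosis, spectral ratio) apply
# to any source decomposition exposed through the same structure.

#' AMUSE source decomposition of one EEG segment
#'
#' Channel means are removed, the data are pre-whitened (eigendecomposition
#' of the sample covariance, retaining components whose eigenvalue exceeds
#' `1e-10` of the largest), and the whitened data are rotated by the
#' eigenvectors of the symmetrised lag-1 covariance.  With no components
#' altered, `mixing %*% sources + mean` restores the segment exactly.
#'
#' @param segment Channels x samples matrix (uV), more samples than
#'   channels.
#' @param lag Covariance lag in samples (default 1).
#' @return Object of class `"amuse_decomposition"`: `sources` (components x
#'   samples, unit variance, ordered by lagged-covariance eigenvalue),
#'   `mixing` (channels x components), `mean` (per channel), `rank`.
#' @export
amuse_decompose <- function(segment, lag = 1L) {
  n <- ncol(segment)
  if (n <= nrow(segment)) stop("segment needs more samples than channels")
  m <- rowMeans(segment)
  X <- segment - m
  C0 <- tcrossprod(X) / n
  eg <- eigen(C0, symmetric = TRUE)
  keep <- eg$values > 1e-10 * eg$values[1L]
  d <- eg$values[keep]; E <- eg$vectors[, keep, drop = FALSE]
  W <- diag(1 / sqrt(d), length(d)) %*% t(E)        # whitening
  Z <- W %*% X
  C1 <- Z[, seq_len(n - lag), drop = FALSE] %*%
    t(Z[, (lag + 1L):n, drop = FALSE]) / (n - lag)
  Cs <- (C1 + t(C1)) / 2
  rot <- eigen(Cs, symmetric = TRUE)
  S <- t(rot$vectors) %*% Z
  A <- E %*% diag(sqrt(d), length(d)) %*% rot$vectors
  structure(list(sources = S, mixing = A, mean = m, rank = length(d)),
            class = "amuse_decomposition")
}

#' Rebuild a segment from a source decomposition
#'
#' @param decomp An `"amuse_decomposition"`.
#' @param remove Integer or logical index of source components to zero out
#'   before reconstruction (default none).
#' @return Channels x samples matrix.
#' @export
amuse_reconstruct <- function(decomp, remove = integer(0)) {
  S <- decomp$sources
  if (length(remove)) S[remove, ] <- 0
  decomp$mixing %*% S + decomp$mean
}

# Per-component statistics used by the rejection criteria.
# Kurtosis is the excess kurtosis of the component after normalisation to
# zero mean and unit standard deviation; a zero-variance component gets
# kurtosis NA (treated as degenerate and flagged).
.component_stats <- function(S, fs = 128) {
  t(apply(S, 1L, function(s) {
    v <- mean((s - mean(s))^2)
    kur <- if (v > 0) mean((s - mean(s))^4) / v^2 - 3 else NA_real_
    p <- spectral_power(s, fs = fs)
    hi <- sum(p[21:40]); lo <- sum(p[5:10])
    pr <- if (lo > 0) hi / lo else Inf
    c(s_max = max(abs(s)), kurtosis = kur, p_ratio = pr)
  }))
}

#' Calibrate artefact-component rejection cuts from reference EEG
#'
#' Decomposes each resting reference segment with AMUSE, pools the
#' per-component statistics, and sets the cuts by the robust three-sigma
#' rule: `Th_s = median + 3 MADN` of the component peak amplitudes,
#' `Th_k = median + 2 MADN` of the component kurtoses (the tighter factor
#' compensates for kurtosis cuts otherwise missing artefact components), and
#' `Th_pr = median + 3 MADN` of the spectral ratios.
#'
#' @param reference_segments List of resting 1-second segments.
#' @param fs Sampling rate (Hz).
#' @return Object of class `"component_thresholds"` with `Th_s`, `Th_k`,
#'   `Th_pr`.
#' @export
calibrate_component_thresholds <- function(reference_segments, fs = 128) {
  stats_all <- do.call(rbind, lapply(reference_segments, function(seg)
    .component_stats(amuse_decompose(seg)$sources, fs = fs)))
  cut <- function(v, k) stats::median(v) + k * madn(v)
  ks <- stats_all[, "kurtosis"]; ks <- ks[is.finite(ks)]
  pr <- stats_all[, "p_ratio"]; pr <- pr[is.finite(pr)]
  structure(list(Th_s = cut(stats_all[, "s_max"], 3),
                 Th_k = cut(ks, 2),
                 Th_pr = cut(pr, 3)),
            class = "component_thresholds")
}

#' Flag artefactual source components
#'
#' A component is flagged when any enabled criterion fires: peak amplitude
#' `max |s_t| > Th_s`; absolute normalised kurtosis `|k| > Th_k`; or — only
#' when a high-frequency artefact was detected in the segment — spectral
#' ratio `P_ratio > Th_pr`, where `P_ratio` is the power at 21-40 Hz over
#' the power at 5-10 Hz.  A zero-variance component is degenerate and is
#' always flagged.
#'
#' @param decomp An `"amuse_decomposition"`.
#' @param cuts A `"component_thresholds"` object.
#' @param high_freq Logical: was a high-frequency artefact detected?
#' @param fs Sampling rate (Hz).
#' @return Logical vector, one flag per component.
#' @export
identify_artefact_components <- function(decomp, cuts, high_freq = FALSE,
                                         fs = 128) {
  st <- .component_stats(decomp$sources, fs = fs)
  flag <- st[, "s_max"] > cuts$Th_s |
    is.na(st[, "kurtosis"]) | abs(st[, "kurtosis"]) > cuts$Th_k
  if (high_freq) flag <- flag | st[, "p_ratio"] > cuts$Th_pr
  unname(flag)
}

#' BSS artefact removal of one segment
#'
#' Decomposes the segment with AMUSE, zeroes the components flagged by
#' [identify_artefact_components()], and reconstructs.  Clean-flagged
#' segments are returned unchanged.
#'
#' @param segment Channels x samples matrix (uV).
#' @param detection `"artefact_detection"` result for the segment.
#' @param cuts `"component_thresholds"` from reference data.
#' @param fs Sampling rate (Hz).
#' @return Denoised segment.
#' @export
denoise_bss <- function(segment, detection, cuts, fs = 128) {
  if (detection$clean) return(segment)
  dec <- amuse_decompose(segment)
  flags <- identify_artefact_components(dec, cuts,
                                        high_freq = detection$high_freq,
                                        fs = fs)
  out <- amuse_reconstruct(dec, remove = which(flags))
  dimnames(out) <- dimnames(segment)
  out
}
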