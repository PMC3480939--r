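# Automatic artefact detection on 1-second multichannel EEG segments.
#
# A segment is a channels x samples numeric matrix (microvolts) with channel
# names as rownames; the default montage covers 15 fronto-central electrodes
# (see eeg_montage()).  Features are computed from the same stationary
# wavelet decomposition later reused by the removal algorithms.

#' Standard 15-channel fronto-central montage
#'
#' Channel names, in package order, of the premotor/sensorimotor montage the
#' pipeline assumes: frontal (F), fronto-central (FC) and central (C) rows.
#' Using only these rows lets detection work without dedicated EOG or EMG
#' electrodes.
#'
#' @return Character vector of 15 channel names.
#' @export
eeg_montage <- function() {
  c("F3", "F1", "Fz", "F2", "F4",
    "FC3", "FC1", "FCz", "FC2", "FC4",
    "C3", "C1", "Cz", "C2", "C4")
}

# Decompose every channel of a segment; returns a list of swt_decomposition.
.decompose_segment <- function(segment, levels = 5L, wavelet = "coif3") {
  lapply(seq_len(nrow(segment)), function(j)
    swt_decompose(segment[j, ], levels = levels, wavelet = wavelet))
}

#' Wavelet and amplitude features of one EEG segment
#'
#' For every decomposition level i and channel j, the mean squared
#' coefficient power `P[i, j] = mean(a[i, j, ]^2)` and the maximum absolute
#' coefficient `M[i, j] = max |a[i, j, ]|`, both over the coefficient span
#' corresponding to the original (un-extended) samples so that boundary
#' padding cannot trigger detection; plus the maximum absolute amplitude
#' `A[j]` of the mean-removed segment.
#'
#' @param segment Channels x samples matrix (uV).
#' @param decomps Optional list of per-channel decompositions (reused from a
#'   previous call); computed if missing.
#' @param levels,wavelet Passed to [swt_decompose()] when decomposing.
#' @return List of class `"eeg_features"`: `P`, `M` ((levels+1) x channels
#'   matrices, rows `d1..d5, a5`), `A` (length-channels vector), `decomps`.
#' @export
eeg_features <- function(segment, decomps = NULL, levels = 5L,
                         wavelet = "coif3") {
  if (is.null(decomps))
    decomps <- .decompose_segment(segment, levels, wavelet)
  nch <- nrow(segment)
  span <- seq_len(ncol(segment))
  P <- M <- matrix(0, levels + 1L, nch,
                   dimnames = list(colnames(decomps[[1L]]$coeffs),
                                   rownames(segment)))
  for (j in seq_len(nch)) {
    cf <- decomps[[j]]$coeffs[span, , drop = FALSE]
    P[, j] <- colMeans(cf^2)
    M[, j] <- apply(abs(cf), 2L, max)
  }
  A <- apply(abs(segment - rowMeans(segment)), 1L, max)
  structure(list(P = P, M = M, A = A, decomps = decomps),
            class = "eeg_features")
}

#' Calibrate detection thresholds from resting reference EEG
#'
#' Thresholds follow the robust three-sigma rule applied per feature, level
#' and channel over the reference segments:
#' `Th = median + 3 * MADN`, floored at a small positive epsilon so power
#' thresholds stay strictly positive.  The reference recording is the
#' resting-state data collected at the start of a session.
#'
#' @param reference_segments List of at least 30 one-second segments
#'   (channels x samples matrices) of artefact-free resting EEG.
#' @param n_ch Channel-count criterion: how many channels must exceed both
#'   their P and M thresholds at a common level before a segment is flagged
#'   (default 5, one third of the montage).
#' @param amplitude_cap Absolute amplitude (uV) any single mean-removed
#'   channel may reach before the segment is flagged outright (default 25).
#' @param levels,wavelet Decomposition settings.
#' @return Object of class `"detection_model"` with `ThP`, `ThM`
#'   ((levels+1) x channels), `ThA` (per channel), `n_ch`, `amplitude_cap`,
#'   `levels`, `wavelet`.
#' @export
calibrate_detection <- function(reference_segments, n_ch = 5L,
                                amplitude_cap = 25, levels = 5L,
                                wavelet = "coif3") {
  if (length(reference_segments) < 30L)
    stop("calibration needs at least 30 reference segments, got ",
         length(reference_segments))
  feats <- lapply(reference_segments, eeg_features,
                  levels = levels, wavelet = wavelet)
  eps <- 1e-6
  rob <- function(v) max(stats::median(v) + 3 * madn(v), eps)
  nl <- levels + 1L
  nch <- nrow(reference_segments[[1L]])
  ThP <- ThM <- matrix(0, nl, nch, dimnames = dimnames(feats[[1L]]$P))
  for (i in seq_len(nl)) for (j in seq_len(nch)) {
    ThP[i, j] <- rob(vapply(feats, function(f) f$P[i, j], 0))
    ThM[i, j] <- rob(vapply(feats, function(f) f$M[i, j], 0))
  }
  ThA <- vapply(seq_len(nch), function(j)
    rob(vapply(feats, function(f) f$A[j], 0)), 0)
  names(ThA) <- rownames(reference_segments[[1L]])
  structure(list(ThP = ThP, ThM = ThM, ThA = ThA, n_ch = as.integer(n_ch),
                 amplitude_cap = amplitude_cap, levels = levels,
                 wavelet = wavelet),
            class = "detection_model")
}

#' Classify one segment as clean / low-frequency / high-frequency artefact
#'
#' A channel "counts" at a level only when BOTH its power and its maximum
#' coefficient exceed their calibrated thresholds there.  Rules:
#' * low-frequency artefact (ocular, electrode or head movement): at least
#'   `n_ch` channels count at the deepest detail level (d5) or at the
#'   approximation level (a5), or any channel's mean-removed amplitude
#'   exceeds the 25 uV cap;
#' * high-frequency artefact (muscle): at least `n_ch` channels count at one
#'   of the first three detail levels (d1-d3).
#'
#' @param features An `"eeg_features"` object (from [eeg_features()]).
#' @param model A calibrated `"detection_model"`.
#' @return Object of class `"artefact_detection"`: logicals `low_freq`,
#'   `high_freq`, `clean`, a `triggering_rule` string (`"count_rule"`,
#'   `"amplitude_cap"` or `"none"`), the per-level/channel exceedance matrix
#'   `exceed`, and the `features` (with decompositions) for reuse by the
#'   removal algorithms.
#' @export
detect_artefacts <- function(features, model) {
  stopifnot(inherits(features, "eeg_features"),
            inherits(model, "detection_model"))
  exceed <- (features$P > model$ThP) & (features$M > model$ThM)
  counts <- rowSums(exceed)                       # per level
  nl <- model$levels + 1L
  low_levels <- c(model$levels, nl)               # d5 and a5
  high_levels <- seq_len(min(3L, model$levels))   # d1..d3
  low_count <- any(counts[low_levels] >= model$n_ch)
  amp_cap <- any(features$A > model$amplitude_cap)
  high <- any(counts[high_levels] >= model$n_ch)
  low <- low_count || amp_cap
  rule <- if (low_count || high) "count_rule"
          else if (amp_cap) "amplitude_cap" else "none"
  structure(list(low_freq = low, high_freq = high, clean = !(low || high),
                 triggering_rule = rule, exceed = exceed,
                 features = features),
            class = "artefact_detection")
}

#' Detect artefacts in a segment (convenience wrapper)
#'
#' Computes features (decomposing each channel once) and applies
#' [detect_artefacts()]; the returned object carries the decompositions so
#' the removal step never recomputes the transform.
#'
#' @param segment Channels x samples matrix (uV).
#' @param model A `"detection_model"`.
#' @return An `"artefact_detection"` object.
#' @export
detect_segment <- function(segment, model) {
  detect_artefacts(eeg_features(segment, levels = model$levels,
                                wavelet = model$wavelet), model)
}
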