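# Quantitative performance metrics: time- and frequency-domain distortion of
# denoised segments, and detection metrics (TPR, FPR, time-normalised FPR)
# for the self-paced pipeline.

#' Periodogram power at integer frequencies
#'
#' Rectangular-window periodogram `P(f) = |X_f|^2 / N` of a signal evaluated
#' at integer frequencies 1..`fmax` Hz.  For a 1-second segment at 128 Hz
#' the bin width is exactly 1 Hz, so these are direct FFT bins.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param fmax Highest frequency returned (default `fs / 2 - 1` but capped
#'   so bins exist).
#' @return Named numeric vector `P[1..fmax]`.
#' @export
spectral_power <- function(x, fs = 128, fmax = NULL) {
  n <- length(x)
  res <- fs / n                       # bin width
  if (is.null(fmax)) fmax <- floor(fs / 2) - 1L
  f <- seq_len(fmax)
  bins <- round(f / res) + 1L
  if (max(bins) > n) stop("signal too short for requested frequencies")
  X <- stats::fft(x)
  p <- Mod(X[bins])^2 / n
  names(p) <- f
  p
}

#' Mean squared error between clean and denoised signals
#'
#' @param clean,denoised Equal-length numeric vectors (uV).
#' @return Scalar MSE (uV^2).
#' @export
mse <- function(clean, denoised) {
  if (length(clean) != length(denoised)) stop("signals differ in length")
  mean((clean - denoised)^2)
}

#' Spectral distortion of a denoised segment
#'
#' `PSDd = sum_f PSD_est(f)^2 / sum_f PSD_clean(f)^2` over f = 1..40 Hz,
#' with the single-window periodogram of [spectral_power()] as the
#' estimator.  The ideal value is 1; values below 1 indicate
#' over-correction (signal removed along with the artefact), values above 1
#' residual artefact or added distortion.  Note the spectral values are
#' squared inside the sums, so the metric scales with the fourth power of
#' amplitude: doubling the denoised signal gives PSDd = 16.
#'
#' @param clean,denoised Equal-length 1-second signals (uV).
#' @param fs Sampling rate (Hz).
#' @return Non-negative scalar.
#' @export
psd_distortion <- function(clean, denoised, fs = 128) {
  if (length(clean) != length(denoised)) stop("signals differ in length")
  pc <- spectral_power(clean, fs, fmax = 40)
  pe <- spectral_power(denoised, fs, fmax = 40)
  den <- sum(pc^2)
  if (den == 0) stop("clean signal has no power in the 1-40 Hz band")
  sum(pe^2) / den
}

#' Time-normalised false positive rate
#'
#' `TNFPR = FPR / 100 * output_rate * 60` false positives per minute: the
#' per-decision false positive percentage converted to a rate that is
#' comparable across systems with different decision rates.
#'
#' @param fpr_pct False positive rate in percent of no-control decisions.
#' @param output_rate Decisions per second (8 for this pipeline).
#' @return False positives per minute.
#' @examples
#' tnfpr(0.42, 8)   # ~2 FPs/min
#' tnfpr(1, 8)      # 4.8 FPs/min
#' @export
tnfpr <- function(fpr_pct, output_rate) {
  if (any(fpr_pct < 0 | fpr_pct > 100)) stop("fpr_pct must lie in [0, 100]")
  if (output_rate <= 0) stop("output_rate must be > 0")
  fpr_pct / 100 * output_rate * 60
}

#' Score a decision stream against a session's ground truth
#'
#' A true positive is declared when the system activates at least once in
#' the window from 0.5 s before to 1.0 s after a switch (intentional
#' control) event; each event counts at most once.  Every decision outside
#' all TP windows is a no-control (NC) trial, and any activation there is a
#' false positive.  Overlapping TP windows (events closer than 1.5 s) are
#' merged for FP accounting.
#'
#' @param decisions 0/1 vector on the decision clock.
#' @param times Decision times in seconds (window end times), same length.
#' @param events Switch event times in seconds (may be empty).
#' @param rate Decisions per second (default 8).
#' @param window TP window around each event, seconds (default
#'   `c(-0.5, 1)`).
#' @return List: `tpr` (percent, `NA` when there are no events), `fpr`
#'   (percent of NC decisions), `tnfpr` (FPs/min), `n_tp`, `n_fp`, `n_ic`,
#'   `n_nc`.
#' @export
score_session <- function(decisions, times, events, rate = 8,
                          window = c(-0.5, 1)) {
  stopifnot(length(decisions) == length(times))
  act <- times[decisions != 0]
  if (length(events)) {
    lo <- events + window[1L]; hi <- events + window[2L]
    hit <- vapply(seq_along(events), function(i)
      any(act >= lo[i] & act <= hi[i]), logical(1L))
    in_any <- function(t) {
      out <- rep(FALSE, length(t))
      for (i in seq_along(events)) out <- out | (t >= lo[i] & t <= hi[i])
      out
    }
    n_tp <- sum(hit)
    tpr <- 100 * n_tp / length(events)
    nc_mask <- !in_any(times)
  } else {
    n_tp <- 0L; tpr <- NA_real_
    nc_mask <- rep(TRUE, length(times))
  }
  n_nc <- sum(nc_mask)
  n_fp <- sum(decisions[nc_mask] != 0)
  fpr <- if (n_nc > 0) 100 * n_fp / n_nc else 0
  list(tpr = tpr, fpr = fpr, tnfpr = tnfpr(fpr, rate),
       n_tp = n_tp, n_fp = n_fp, n_ic = length(events), n_nc = n_nc)
}

#' Inter-trial variability of denoised segments
#'
#' Population standard deviation, across trials, of two per-trial summary
#' statistics of the denoised signal: its variance (`sigma_var`, uV^2) and
#' its max-minus-min range (`sigma_maxmin`, uV).  Consistent denoisers have
#' small values.
#'
#' @param trials List of numeric vectors (>= 2 denoised trials).
#' @return Named list `sigma_maxmin`, `sigma_var`.
#' @export
inter_trial_variability <- function(trials) {
  if (length(trials) < 2L) stop("need at least 2 trials")
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  vars <- vapply(trials, function(x) mean((x - mean(x))^2), 0)
  rngs <- vapply(trials, function(x) diff(range(x)), 0)
  list(sigma_maxmin = pop_sd(rngs), sigma_var = pop_sd(vars))
}
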