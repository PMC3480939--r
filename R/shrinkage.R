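# Wavelet coefficient shrinkage and the adaptive threshold update.
#
# Convention used throughout: the shrinkage function delta() extracts the
# ARTEFACT part of a coefficient vector (large coefficients are assumed to be
# artefactual), a_bar = delta(a); the part retained as brain signal is the
# complement a_ring = a - a_bar.  All four shrinkage kinds share this split,
# so every denoiser in the package is compared on identical semantics.

#' Normalised median absolute deviation
#'
#' `MADN(x) = median(|x - median(x)|) / 0.6745`, a robust estimate of the
#' standard deviation that is unbiased for normally distributed data and
#' insensitive to the large outlying coefficients artefacts produce.
#'
#' @param x Non-empty numeric vector.
#' @return Non-negative scalar; 0 when at least half the values equal the
#'   median.
#' @examples
#' madn(c(1, 2, 3, 4, 100))   # 1 / 0.6745
#' @export
madn <- function(x) {
  if (length(x) == 0L) stop("madn() needs a non-empty vector")
  stats::median(abs(x - stats::median(x))) / 0.6745
}

#' Universal wavelet threshold
#'
#' `T0 = sigma * sqrt(2 log N)` with `sigma = MADN(x)` and `N = length(x)`:
#' the classical level-dependent starting threshold, computed robustly from
#' the coefficients themselves.
#'
#' @param x Coefficient vector, length >= 2.
#' @return Non-negative scalar threshold (same units as `x`).
#' @export
universal_threshold <- function(x) {
  n <- length(x)
  if (n < 2L) stop("universal threshold needs at least 2 coefficients")
  madn(x) * sqrt(2 * log(n))
}

#' Split wavelet coefficients into artefact and signal parts
#'
#' Applies one of four shrinkage functions at threshold `T` and returns both
#' the artefact estimate `a_bar = delta(a)` and the retained signal
#' `a_ring = a - a_bar`.  Sub-threshold coefficients (`|a| <= T`) are always
#' passed through untouched (`a_bar = 0`).
#'
#' * `hard`: `delta(x) = x` for `|x| > T` (remove outright).
#' * `soft`: `delta(x) = x - sign(x) T` for `|x| > T` (signal clipped at T).
#' * `garrote`: non-negative garrote, `delta(x) = x - T^2 / x` — continuous
#'   like soft but with smaller bias on large coefficients.
#' * `sbss`: smooth sigmoid-based shrinkage,
#'   `delta(x) = sign(x) (|x| - T) / (1 + exp(-tau (|x| - lambda)))`, with
#'   threshold height `lambda > T` and attenuation rate `tau` controlling
#'   how sharply attenuation turns on between T and lambda.
#'
#' @param a Numeric coefficient vector.
#' @param T Threshold, `>= 0`.
#' @param kind One of `"hard"`, `"soft"`, `"garrote"`, `"sbss"`.
#' @param lambda,tau SBSS parameters; defaults `lambda = 2 T`, `tau = 1`.
#' @return List with `a_bar`, `a_ring` (numeric, `a_bar + a_ring == a`
#'   exactly) and the applied `T`.
#' @export
shrink_coefficients <- function(a, T, kind = c("garrote", "hard", "soft", "sbss"),
                                lambda = 2 * T, tau = 1) {
  kind <- match.arg(kind)
  if (T < 0) stop("threshold must be >= 0")
  big <- abs(a) > T
  a_bar <- numeric(length(a))
  if (any(big)) {
    x <- a[big]
    a_bar[big] <- switch(kind,
      hard = x,
      soft = x - sign(x) * T,
      garrote = x - T^2 / x,            # |x| > T >= 0 so x != 0
      sbss = {
        if (lambda <= T && T > 0) stop("sbss requires lambda > T")
        sign(x) * (abs(x) - T) / (1 + exp(-tau * (abs(x) - lambda)))
      })
  }
  list(a_bar = a_bar, a_ring = a - a_bar, T = T)
}

# Retained-signal power P_ring(T) over the index span, without materialising
# the split.  o$x2 etc. are precomputed by .adapt_precompute(); sbss falls
# back to direct evaluation on the over-threshold tail.
.adapt_precompute <- function(x) {
  ax <- abs(x)
  o <- order(ax)
  ax <- ax[o]
  x2 <- (x[o])^2
  list(ax = ax, cum_x2 = cumsum(x2), cum_inv2 = cumsum(1 / pmax(x2, .Machine$double.xmin)),
       n = length(x))
}

.p_ring_fast <- function(pre, T, kind, tau) {
  k <- findInterval(T, pre$ax)            # coefficients with |x| <= T
  below <- if (k > 0L) pre$cum_x2[k] else 0
  m <- pre$n - k                          # count above threshold
  tot <- switch(kind,
    hard = below,
    soft = below + m * T^2,
    garrote = below + T^4 *
      (pre$cum_inv2[pre$n] - if (k > 0L) pre$cum_inv2[k] else 0),
    sbss = {
      if (m == 0L) below else {
        axt <- pre$ax[(k + 1L):pre$n]
        w <- 1 / (1 + exp(-tau * (axt - 2 * T)))
        below + sum((axt - (axt - T) * w)^2)
      }
    })
  tot / pre$n
}

#' Adapt one level's threshold until the retained power is plausible
#'
#' Implements the adaptive rule at the heart of the denoiser.  The threshold
#' starts at the universal threshold `T0` of the level's coefficients; the
#' coefficients are split with [shrink_coefficients()]; while the power of
#' the retained (signal) part over `span` still exceeds the detection
#' threshold `ThP` — i.e. artefact energy is still present — the threshold
#' is lowered geometrically, `T <- T - mu * T`, and the split recomputed.
#'
#' Termination: for the hard, soft and garrote kinds the retained power is
#' monotone in T and tends to 0 as T tends to 0, so the loop always reaches
#' `P_ring <= ThP`; a hard iteration cap (default 500) and a floor at
#' `1e-9 * T0` guard the SBSS kind, whose retained power has a positive
#' floor.  A capped adaptation is flagged, never silent.
#'
#' @param a Coefficient vector for one decomposition level of one channel
#'   (full extended length).
#' @param ThP Detection power threshold for this level/channel (uV^2), > 0.
#' @param kind Shrinkage kind, see [shrink_coefficients()].
#' @param mu Learning rate in (0, 1); defaults per [default_mu()].
#' @param span Indices over which the stopping power is measured (the
#'   coefficient span of the un-extended segment), default all of `a`.
#' @param max_iter Iteration cap per level.
#' @param tau0_scale SBSS attenuation rate is fixed at `tau0_scale / T0`.
#' @return List: `split` (final [shrink_coefficients()] result), `T` (final
#'   threshold), `T0`, `iterations`, `p_ring`, `capped` (logical).
#' @export
adapt_level <- function(a, ThP, kind = "garrote", mu = default_mu(kind),
                        span = seq_along(a), max_iter = 500L,
                        tau0_scale = 10) {
  if (ThP <= 0) stop("ThP must be > 0 (calibration floors thresholds)")
  if (mu <= 0 || mu >= 1) stop("mu must lie in (0, 1)")
  T0 <- universal_threshold(a[span])
  tau <- if (T0 > 0) tau0_scale / T0 else 1
  pre <- .adapt_precompute(a[span])
  T <- T0
  iter <- 0L
  p <- .p_ring_fast(pre, T, kind, tau)
  while (p > ThP && iter < max_iter && T > 1e-9 * T0) {
    T <- T - mu * T
    iter <- iter + 1L
    p <- .p_ring_fast(pre, T, kind, tau)
  }
  split <- shrink_coefficients(a, T, kind, lambda = 2 * T, tau = tau)
  list(split = split, T = T, T0 = T0, iterations = iter, p_ring = p,
       capped = p > ThP)
}

#' Default learning rate per shrinkage kind
#'
#' 0.1 for the hard, garrote and SBSS kinds; 0.5 for soft shrinkage, whose
#' heavier attenuation tolerates (and needs) larger steps.
#'
#' @param kind Shrinkage kind.
#' @return Scalar learning rate.
#' @export
default_mu <- function(kind = c("garrote", "hard", "soft", "sbss")) {
  kind <- match.arg(kind)
  if (kind == "soft") 0.5 else 0.1
}
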