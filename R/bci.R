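# Pseudo-online self-paced BCI pipeline: sliding-window segmentation at 8
# decisions/s, bipolar derivation, FFT band-power features, stepwise LDA
# feature selection, LDA scoring, moving average, debounce and dwell gating.

#' The 30 bipolar derivations of the 15-channel montage
#'
#' Differences between adjacent monopolar channels, in the fixed pipeline
#' order (each derivation is first channel minus second).
#'
#' @return A 30 x 2 character matrix of channel-name pairs.
#' @export
bipolar_pairs <- function() {
  p <- c("Cz-C1", "Cz-C2", "Cz-C3", "Cz-C4", "C1-C2", "C1-C4", "C1-C3",
         "C2-C3", "C2-C4", "C3-C4", "FCz-Cz", "FC1-C1", "FC2-C2", "FC3-C3",
         "FC4-C4", "Fz-FCz", "F1-FC1", "F2-FC2", "F3-FC3", "F4-FC4",
         "FCz-FC1", "FCz-FC2", "FCz-FC3", "FCz-FC4", "FC1-FC2", "FC1-FC4",
         "FC1-FC3", "FC2-FC3", "FC2-FC4", "FC3-FC4")
  out <- do.call(rbind, strsplit(p, "-", fixed = TRUE))
  dimnames(out) <- list(p, c("plus", "minus"))
  out
}

#' Sliding-window segmentation at 8 segments per second
#'
#' One-second windows (128 samples at 128 Hz) with 87.5% overlap: the step
#' is 16 samples, so 8 segments are produced per covered second and a
#' stream of `s` whole seconds yields `1 + (s - 1) * 8` segments.
#'
#' @param n_samples Number of samples in the stream (or a channels x
#'   samples matrix, whose column count is used).
#' @param window,step Window and step sizes in samples.
#' @return Integer vector of window start indices (1-based); empty when the
#'   stream is shorter than one window.
#' @export
segment_starts <- function(n_samples, window = 128L, step = 16L) {
  if (is.matrix(n_samples)) n_samples <- ncol(n_samples)
  n_samples <- as.integer(n_samples)
  if (n_samples < window) return(integer(0))
  seq.int(1L, n_samples - as.integer(window) + 1L, by = as.integer(step))
}

#' Bipolar derivation of one segment
#'
#' @param segment Channels x samples matrix with the montage channel names
#'   as rownames.
#' @return 30 x samples matrix, one row per [bipolar_pairs()] derivation.
#' @export
bipolar_derive <- function(segment) {
  pairs <- bipolar_pairs()
  missing <- setdiff(unique(c(pairs)), rownames(segment))
  if (length(missing))
    stop("segment is missing channel(s): ", paste(missing, collapse = ", "))
  out <- segment[pairs[, 1L], , drop = FALSE] -
    segment[pairs[, 2L], , drop = FALSE]
  rownames(out) <- rownames(pairs)
  out
}

#' FFT band-power feature vector of one segment
#'
#' Periodogram power of each bipolar derivation at the integer frequencies
#' 1..35 Hz (movement-related potentials plus mu and beta bands), stacked
#' derivation-major into a vector of 30 x 35 = 1050 features.
#'
#' @param bipolar 30 x samples matrix from [bipolar_derive()].
#' @param fs Sampling rate (Hz).
#' @return Numeric vector of length 1050, names `<pair>.<freq>`.
#' @export
psd_features <- function(bipolar, fs = 128) {
  P <- t(apply(bipolar, 1L, spectral_power, fs = fs, fmax = 35))
  v <- as.vector(t(P))
  names(v) <- as.vector(t(outer(rownames(bipolar), 1:35, paste, sep = ".")))
  v
}

#' Stepwise feature selection for two-class discrimination
#'
#' Classical forward-backward stepwise selection on the partial F statistic
#' (equivalent, for two classes, to stepwise discriminant analysis): at each
#' step the candidate with the largest partial F enters if its p-value is at
#' most `p_enter`; after every entry, included features whose partial F
#' p-value has risen to `p_remove` or above are dropped.  Selection stops
#' when no candidate qualifies or `max_features` are included.
#'
#' @param x Numeric feature matrix (observations x features).
#' @param y Two-class labels (0/1, logical, or a two-level factor).
#' @param p_enter,p_remove Entry and removal p-value cuts (0.05 / 0.10).
#' @param max_features Hard cap on the number of selected features (140).
#' @return Integer vector of selected column indices, in entry order.
#' @export
stepwise_select <- function(x, y, p_enter = 0.05, p_remove = 0.10,
                            max_features = 140L) {
  y <- as.numeric(as.factor(y)) - 1
  if (length(unique(y)) != 2L) stop("both classes must be present")
  n <- nrow(x); p <- ncol(x)
  yr <- y - mean(y)
  xr <- sweep(x, 2L, colMeans(x))
  selected <- integer(0)
  available <- rep(TRUE, p)

  refit_p <- function(sel) {
    # partial-F p-value of each included feature from the full fit
    X <- cbind(1, x[, sel, drop = FALSE])
    qr_ <- qr(X)
    beta <- qr.coef(qr_, y)
    res <- y - X %*% beta
    df <- n - length(sel) - 1L
    sigma2 <- sum(res^2) / df
    R <- qr.R(qr_)
    cov_diag <- diag(chol2inv(R)) * sigma2
    tval <- beta / sqrt(cov_diag)
    2 * stats::pt(-abs(tval[-1L]), df)
  }
  reresidualise <- function(sel) {
    X <- cbind(1, x[, sel, drop = FALSE])
    qr_ <- qr(X)
    yr <<- qr.resid(qr_, y)
    xr <<- qr.resid(qr_, x)
    xr[, sel] <<- 0
  }

  repeat {
    if (length(selected) >= max_features) break
    ssx <- colSums(xr^2)
    ssy <- sum(yr^2)
    if (ssy <= 0) break
    r2 <- (crossprod(xr, yr)^2) / (pmax(ssx, 1e-300) * ssy)
    r2[!available | ssx < 1e-10 * max(ssx)] <- -Inf
    k <- which.max(r2)
    df <- n - length(selected) - 2L
    if (df < 1L || r2[k] <= 0) break
    Fk <- r2[k] * df / (1 - r2[k])
    if (stats::pf(Fk, 1, df, lower.tail = FALSE) > p_enter) break
    selected <- c(selected, k)
    available[k] <- FALSE
    # orthogonalise the residual space against the entered feature
    v <- xr[, k] / sqrt(sum(xr[, k]^2))
    yr <- yr - v * sum(v * yr)
    xr <- xr - v %*% crossprod(v, xr)
    # backward sweep
    repeat {
      if (length(selected) < 2L) break
      pv <- refit_p(selected)
      worst <- which.max(pv)
      if (pv[worst] < p_remove) break
      available[selected[worst]] <- TRUE
      selected <- selected[-worst]
      reresidualise(selected)
    }
  }
  selected
}

#' Moving average, threshold, and debounce of an LDA score stream
#'
#' The continuous discriminant scores are smoothed with a 2-sample moving
#' average, thresholded into 0/1 states, optionally blocked (forced 0, e.g.
#' for artefact rejection), and debounced: each emitted activation is
#' followed by `t_db` forced no-control decisions, guaranteeing at least
#' `t_db / 8` seconds between consecutive activations.
#'
#' @param scores Numeric LDA score stream (higher = intentional control).
#' @param threshold Decision threshold on the smoothed score.
#' @param t_db Debounce period in decision samples (default 8).
#' @param block Optional logical vector: decisions forced to 0 (applied
#'   before debouncing).
#' @param ma_len Moving-average length in samples (default 2).
#' @return Integer 0/1 decision vector.
#' @export
classify_stream <- function(scores, threshold, t_db = 8L, block = NULL,
                            ma_len = 2L) {
  n <- length(scores)
  if (n == 0L) return(integer(0))
  sm <- scores
  if (ma_len > 1L && n > 1L)
    sm <- stats::filter(c(rep(scores[1L], ma_len - 1L), scores),
                        rep(1 / ma_len, ma_len), sides = 1L)[ma_len:(n + ma_len - 1L)]
  raw <- as.integer(sm > threshold)
  if (!is.null(block)) raw[block] <- 0L
  out <- integer(n)
  refractory <- 0L
  for (i in seq_len(n)) {
    if (refractory > 0L) {
      refractory <- refractory - 1L
    } else if (raw[i] == 1L) {
      out[i] <- 1L
      refractory <- t_db
    }
  }
  out
}

#' Suppress decisions outside qualifying gaze dwell periods
#'
#' The BCI sleeps unless the point of gaze is inside a clickable fixation
#' interval and has dwelt there for at least `t_dwell` seconds: a decision
#' at time t survives only if some clickable interval `[start, end]`
#' contains t with `t >= start + t_dwell`.  With `t_dwell = 0` gating
#' requires only gaze-on-clickable.
#'
#' @param decisions 0/1 decision vector.
#' @param times Decision times (s), same length.
#' @param gaze Data frame with `start`, `end`, `clickable`.
#' @param t_dwell Dwell requirement in seconds.
#' @return Gated 0/1 decision vector.
#' @export
dwell_gate <- function(decisions, times, gaze, t_dwell = 0) {
  gz <- gaze[gaze$clickable, , drop = FALSE]
  ok <- rep(FALSE, length(times))
  for (i in seq_len(nrow(gz)))
    ok <- ok | (times >= gz$start[i] + t_dwell & times <= gz$end[i])
  decisions * as.integer(ok)
}
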