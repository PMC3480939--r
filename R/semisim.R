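# Semi-simulated EEG benchmark generator.
#
# Surrogate clean EEG (1/f background plus a per-channel 8-12 Hz idle
# rhythm), band-limited artefact templates (Kaiser-window FIR band-passed
# noise), mixing at a controlled worst-channel signal-to-noise ratio, and
# full synthetic self-paced sessions with embedded intentional-control
# signatures.  Every generator is deterministic given (parameters, seed).

.set_seed <- function(seed) if (!is.null(seed)) set.seed(seed)

# ---- FIR design -----------------------------------------------------------

#' Kaiser window
#'
#' `w[n] = I0(beta sqrt(1 - (2n/(M-1) - 1)^2)) / I0(beta)` for
#' `n = 0..M-1`, where I0 is the zeroth-order modified Bessel function.
#'
#' @param m Window length.
#' @param beta Shape parameter; `beta = 0.1102 (A - 8.7)` gives roughly
#'   `A` dB of stopband attenuation (5.653 for 60 dB).
#' @return Numeric vector of length `m`.
#' @export
kaiser_window <- function(m, beta) {
  n <- seq_len(m) - 1L
  r <- 2 * n / (m - 1) - 1
  besselI(beta * sqrt(pmax(0, 1 - r^2)), 0) / besselI(beta, 0)
}

#' Kaiser-window FIR band-pass filter
#'
#' Windowed-sinc linear-phase band-pass design: the ideal band-pass impulse
#' response tapered by a Kaiser window.
#'
#' @param numtaps Filter length (odd recommended; default 513 gives a
#'   transition width of about 0.7 Hz at 128 Hz for 60 dB attenuation —
#'   narrow enough that a 1-3 Hz pass band actually exists).
#' @param f_lo,f_hi Band edges (Hz).
#' @param fs Sampling rate (Hz).
#' @param beta Kaiser shape parameter (default 5.653, ~60 dB stopband).
#' @return Numeric vector of filter coefficients.
#' @export
fir_bandpass <- function(numtaps = 513L, f_lo, f_hi, fs = 128, beta = 5.653) {
  if (f_lo <= 0 || f_hi <= f_lo || f_hi >= fs / 2)
    stop("band edges must satisfy 0 < f_lo < f_hi < fs/2")
  m <- (seq_len(numtaps) - 1L) - (numtaps - 1) / 2
  sinc <- function(f) ifelse(m == 0, 2 * f / fs, sin(2 * pi * f * m / fs) / (pi * m))
  (sinc(f_hi) - sinc(f_lo)) * kaiser_window(numtaps, beta)
}

# Linear convolution via FFT; returns the central "steady-state" n samples.
.filter_noise <- function(noise, h, n) {
  L <- length(noise) + length(h) - 1L
  nf <- stats::nextn(L, 2)
  y <- Re(stats::fft(stats::fft(c(noise, numeric(nf - length(noise)))) *
                     stats::fft(c(h, numeric(nf - length(h)))),
                     inverse = TRUE)) / nf
  y[length(h) + seq_len(n)]
}

# ---- generators -----------------------------------------------------------

# Spectrally shaped Gaussian noise: white noise whose FFT is multiplied by
# shape(f) (f in Hz, one-sided), hermitian-symmetrised, normalised to the
# requested RMS.
.shaped_noise <- function(n, fs, shape, rms) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                 # fold to one-sided frequency
  X <- X * shape(f)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x <- x - mean(x)
  r <- sqrt(mean(x^2))
  if (r > 0) x * rms / r else x
}

#' Generate surrogate clean EEG
#'
#' Each channel is the sum of 1/f-shaped ("pink") background noise and an
#' independent narrow-band 8-12 Hz idle-rhythm component (Gaussian spectral
#' bump centred on 10 Hz).  Default amplitudes (pink RMS 3 uV, rhythm RMS
#' 4 uV — a pronounced idle rhythm, total RMS 5 uV) keep segment peak
#' amplitudes comfortably below the 25 uV detection cap, as resting EEG
#' from fronto-central channels should be.
#'
#' @param n_channels Number of channels (default 15; rownames from
#'   [eeg_montage()] when 15).
#' @param duration Length in seconds (>= 1).
#' @param fs Sampling rate (Hz).
#' @param noise_rms,alpha_rms Component RMS amplitudes (uV).
#' @param seed Integer seed (optional).
#' @return Channels x samples matrix (uV).
#' @export
sim_clean_eeg <- function(n_channels = 15L, duration, fs = 128,
                          noise_rms = 3, alpha_rms = 4, seed = NULL) {
  if (duration < 1) stop("duration must be at least 1 second")
  .set_seed(seed)
  n <- round(duration * fs)
  pink <- function(f) ifelse(f < 1, 1, 1 / sqrt(f))
  bump <- function(f) exp(-(f - 10)^2 / 2)
  x <- t(vapply(seq_len(n_channels), function(j)
    .shaped_noise(n, fs, pink, noise_rms) +
      .shaped_noise(n, fs, bump, alpha_rms),
    numeric(n)))
  if (n_channels == 15L) rownames(x) <- eeg_montage()
  x
}

#' Generate a band-limited artefact template
#'
#' Ocular (eye-blink) artefacts are simulated as random noise band-passed to
#' 1-3 Hz, muscle artefacts as random noise band-passed to 20-60 Hz, both
#' with a Kaiser-window FIR filter.  The template is zero-mean and unit-RMS;
#' [mix_artefact()] sets its physical scale.
#'
#' @param kind `"ocular"` or `"muscle"`.
#' @param n Template length in samples (must be at least the filter length).
#' @param fs Sampling rate (Hz).
#' @param numtaps,beta FIR design parameters, see [fir_bandpass()].
#' @param seed Integer seed (optional).
#' @return Numeric vector of length `n`.
#' @export
sim_artefact <- function(kind = c("ocular", "muscle"), n, fs = 128,
                         numtaps = 513L, beta = 5.653, seed = NULL) {
  kind <- match.arg(kind)
  if (n < numtaps) stop("template length must be >= numtaps = ", numtaps)
  .set_seed(seed)
  band <- switch(kind, ocular = c(1, 3), muscle = c(20, 60))
  if (band[2L] >= fs / 2) band[2L] <- fs / 2 - 1
  h <- fir_bandpass(numtaps, band[1L], band[2L], fs, beta)
  x <- .filter_noise(stats::rnorm(n + 2L * numtaps), h, n)
  x <- x - mean(x)
  x / sqrt(mean(x^2))
}

#' Default per-channel artefact contamination profile
#'
#' Ocular artefacts project most strongly onto the frontal row and fade
#' towards the central row (row gains 1.0 / 0.75 / 0.5 for the F / FC / C
#' rows of the 15-channel montage — blinks remain clearly visible at the
#' vertex); muscle artefacts are taken spatially uniform.
#'
#' @param kind `"ocular"` or `"muscle"`.
#' @param n_channels Number of channels (default 15).
#' @return Numeric gain vector.
#' @export
artefact_gain_profile <- function(kind = c("ocular", "muscle"),
                                  n_channels = 15L) {
  kind <- match.arg(kind)
  if (kind == "muscle") return(rep(1, n_channels))
  if (n_channels == 15L) rep(c(1, 0.75, 0.5), each = 5L)
  else seq(1, 0.5, length.out = n_channels)
}

#' Mix an artefact template into a clean segment at a target SNR
#'
#' The template is circularly shifted, scaled per channel by `gains`, and
#' globally rescaled so that the channel with the largest gain has exactly
#' the target signal-to-noise ratio
#' `10 log10(P_clean / P_artefact) = target_snr_db` (default 0 dB, the
#' worst-channel convention of the benchmark).
#'
#' @param clean Channels x samples clean segment (uV).
#' @param template Artefact template (length >= segment samples).
#' @param gains Per-channel contamination gains; default per-kind profile.
#' @param shift Circular shift of the template in samples.
#' @param target_snr_db Target SNR on the max-gain channel (dB).
#' @param kind Artefact kind label (used for the default gains).
#' @return Object of class `"semisim_trial"`: `clean`, `artefact` (the added
#'   channels x samples contamination), `mixed`, `gains`, `shift`, `kind`,
#'   `snr_db`.
#' @export
mix_artefact <- function(clean, template, gains = NULL, shift = 0L,
                         target_snr_db = 0, kind = c("ocular", "muscle")) {
  kind <- match.arg(kind)
  if (is.null(gains)) gains <- artefact_gain_profile(kind, nrow(clean))
  if (length(gains) != nrow(clean)) stop("one gain per channel required")
  if (max(gains) <= 0) stop("max gain must be > 0")
  n <- ncol(clean)
  if (length(template) < n) stop("template shorter than segment")
  idx <- ((seq_len(n) - 1L + shift) %% length(template)) + 1L
  a0 <- template[idx]
  pa <- mean(a0^2)
  if (pa == 0) stop("artefact template has zero power")
  j <- which.max(gains)
  pc <- mean(clean[j, ]^2)
  alpha <- sqrt(pc / (gains[j]^2 * pa) * 10^(-target_snr_db / 10))
  artefact <- alpha * outer(gains, a0)
  rownames(artefact) <- rownames(clean)
  mixed <- clean + artefact
  artefact <- mixed - clean       # so the ledger mixed - clean is bit-exact
  snr <- 10 * log10(pc / mean(artefact[j, ]^2))
  structure(list(clean = clean, artefact = artefact, mixed = mixed,
                 gains = gains, shift = shift, kind = kind, snr_db = snr),
            class = "semisim_trial")
}

#' Generate resting reference segments for calibration
#'
#' Clean surrogate EEG cut into non-overlapping 1-second segments, standing
#' in for the resting-state recording collected at the start of a session.
#'
#' @param n_channels Number of channels.
#' @param n_segments Number of 1-second segments (default 120, two minutes).
#' @param fs Sampling rate (Hz).
#' @param seed Integer seed (optional).
#' @param ... Passed to [sim_clean_eeg()].
#' @return List of channels x fs matrices.
#' @export
sim_reference <- function(n_channels = 15L, n_segments = 120L, fs = 128,
                          seed = NULL, ...) {
  eeg <- sim_clean_eeg(n_channels, duration = n_segments, fs = fs,
                       seed = seed, ...)
  lapply(seq_len(n_segments), function(k)
    eeg[, (k - 1L) * fs + seq_len(fs), drop = FALSE])
}

#' Generate a full synthetic self-paced session
#'
#' A continuous recording with `n_ic` switch (intentional-control) events.
#' Each event carries a physiologically styled, distinguishable IC
#' signature over the second following it: the 8-12 Hz idle rhythm of the
#' central and fronto-central rows is attenuated by `erd_depth` (an
#' event-related desynchronisation, a band-power decrease that survives
#' amplitude-thresholding artefact removal), and a stereotyped slow
#' movement-related potential (a smooth biphasic 1-3 Hz deflection of RMS
#' `mrp_rms`) is added over a small set of central channels (FCz, Cz, C1,
#' C2 — deliberately fewer than the detector's channel-count criterion, so
#' the potential itself never trips artefact detection).  The slow
#' potential overlaps the ocular artefact band, as real movement-related
#' activity does: contamination therefore genuinely degrades an
#' artefact-ignorant classifier.
#'
#' Artefacts (0 dB worst-channel SNR, ocular or muscle at random) are
#' injected into a fraction `contamination_ic_pct` of the IC windows and
#' into 1-second slots covering `contamination_nc_pct` of the remaining
#' time; the defaults are the contamination rates reported for real
#' self-paced sessions (48.4% of IC and 90.2% of NC trials).
#'
#' Gaze: each event is covered by a clickable fixation interval
#' `[event - 2, event + 1.5]` s; an equal number of 3-second clickable
#' distractor fixations is placed between events so that false positives
#' remain possible during no-control periods.
#'
#' @param duration Session length in seconds.
#' @param n_ic Number of switch events (>= 1).
#' @param contamination_ic_pct,contamination_nc_pct Contamination rates in
#'   percent (0-100).
#' @param erd_depth Fractional idle-rhythm attenuation during IC windows
#'   (0-1, default 0.4; moderate, so that the
#'   slow potential carries a decisive share of the discriminable signal).
#' @param mrp_rms RMS amplitude (uV) of the slow movement-related potential
#'   on its strongest channel (Cz), default 3.5.
#' @param gain_jitter Log-normal sd of the per-event multiplicative jitter
#'   applied to the artefact gain profile (default 0.4): successive blinks
#'   and muscle bursts do not share one fixed topography.
#' @param dwell_time Dwell requirement carried in the session (seconds).
#' @param fs Sampling rate (Hz).
#' @param noise_rms,alpha_rms Background amplitudes, as in
#'   [sim_clean_eeg()] (defaults match, so reference recordings calibrate
#'   detection correctly for session data).
#' @param seed Integer seed (optional).
#' @return Object of class `"bci_session"`: `eeg` (channels x samples),
#'   `fs`, `events` (times, s), `gaze` (data frame `start`, `end`,
#'   `clickable`), `dwell_time`, `contamination` (data frame `start`,
#'   `kind`, `trial` in IC/NC), `seed`.
#' @export
sim_session <- function(duration, n_ic, contamination_ic_pct = 48.4,
                        contamination_nc_pct = 90.2, erd_depth = 0.4,
                        mrp_rms = 3.5, gain_jitter = 0.4, dwell_time = 0,
                        fs = 128, noise_rms = 3, alpha_rms = 4,
                        seed = NULL) {
  if (n_ic < 1L) stop("n_ic must be >= 1")
  for (p in c(contamination_ic_pct, contamination_nc_pct))
    if (p < 0 || p > 100) stop("contamination rates must lie in [0, 100]")
  if (duration < 8 * n_ic + 10)
    stop("duration too short for ", n_ic, " well-separated events")
  .set_seed(seed)
  n <- round(duration * fs)

  # event times on a jittered grid, >= 5 s from the edges
  grid <- seq(5, duration - 5, length.out = n_ic)
  events <- sort(grid + stats::runif(n_ic, -0.5, 0.5))

  # idle-rhythm envelope: ERD during [event, event + 1] on the FC and C rows
  t <- (seq_len(n) - 1L) / fs
  env <- rep(1, n)
  for (e in events) env[t >= e & t < e + 1] <- 1 - erd_depth
  erd_channels <- 6:15                      # FC and C rows of the montage
  pink <- function(f) ifelse(f < 1, 1, 1 / sqrt(f))
  bump <- function(f) exp(-(f - 10)^2 / 2)
  eeg <- matrix(0, 15L, n, dimnames = list(eeg_montage(), NULL))
  for (j in 1:15) {
    alpha <- .shaped_noise(n, fs, bump, alpha_rms)
    if (j %in% erd_channels) alpha <- alpha * env
    eeg[j, ] <- .shaped_noise(n, fs, pink, noise_rms) + alpha
  }

  # slow movement-related potential: stereotyped biphasic 1-3 Hz deflection
  # on four central channels (below the detector's channel-count criterion)
  s01 <- (seq_len(fs) - 1L) / fs
  mrp_wave <- sin(2 * pi * 1.5 * s01) * (1 - cos(2 * pi * s01)) / 2
  mrp_wave <- mrp_wave / sqrt(mean(mrp_wave^2)) * mrp_rms
  mrp_channels <- c(FCz = 8L, Cz = 13L, C1 = 12L, C2 = 14L)
  mrp_scale <- c(0.8, 1, 0.7, 0.7)
  for (e in events) {
    idx <- round(e * fs) + seq_len(fs)
    eeg[mrp_channels, idx] <- eeg[mrp_channels, idx] +
      outer(mrp_scale, mrp_wave)
  }

  # contamination bookkeeping on 1-second windows
  contam <- list()
  add_artefact <- function(eeg, start_s, trial) {
    idx <- round(start_s * fs) + seq_len(fs)
    kind <- sample(c("ocular", "muscle"), 1L)
    tpl <- sim_artefact(kind, n = 640L)
    gains <- artefact_gain_profile(kind) *
      exp(stats::rnorm(15L, 0, gain_jitter))
    trial_mix <- mix_artefact(eeg[, idx, drop = FALSE], tpl, gains = gains,
                              shift = sample(0:511, 1L), kind = kind)
    eeg[, idx] <- trial_mix$mixed
    contam[[length(contam) + 1L]] <<- data.frame(start = start_s,
                                                 kind = kind, trial = trial)
    eeg
  }
  n_cont_ic <- round(contamination_ic_pct / 100 * n_ic)
  for (e in events[sample.int(n_ic, n_cont_ic)])
    eeg <- add_artefact(eeg, e, "IC")

  slots <- seq(0L, floor(duration) - 1L)
  near_event <- vapply(slots, function(s)
    any(events > s - 2 & events < s + 2), logical(1L))
  nc_slots <- slots[!near_event]
  n_cont_nc <- round(contamination_nc_pct / 100 * length(nc_slots))
  for (s in nc_slots[sample.int(length(nc_slots), n_cont_nc)])
    eeg <- add_artefact(eeg, s, "NC")

  # gaze: clickable fixation on each event plus clickable distractors
  gaze <- data.frame(start = events - 2, end = events + 1.5,
                     clickable = TRUE)
  mids <- (utils::head(events, -1) + events[-1]) / 2
  distract <- data.frame(start = mids - 1.5, end = mids + 1.5,
                         clickable = TRUE)
  gaze <- rbind(gaze, distract)
  gaze <- gaze[order(gaze$start), ]
  keep <- c(TRUE, gaze$start[-1] >= utils::head(gaze$end, -1))
  gaze <- gaze[keep, ]
  rownames(gaze) <- NULL

  structure(list(eeg = eeg, fs = fs, events = events, gaze = gaze,
                 dwell_time = dwell_time,
                 contamination = if (length(contam)) do.call(rbind, contam)
                                 else data.frame(start = numeric(0),
                                                 kind = character(0),
                                                 trial = character(0)),
                 seed = seed),
            class = "bci_session")
}
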