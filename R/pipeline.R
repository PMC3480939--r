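# End-to-end pseudo-online runner: artefact handling per segment, feature
# stream, classifier training with validation-based threshold selection, and
# session scoring.

#' Calibrate every artefact-handling model from resting reference data
#'
#' Bundles the detection thresholds, the fixed reference wavelet thresholds
#' and the BSS component-rejection cuts, so each denoising method can be
#' selected by name downstream.
#'
#' @param reference_segments List of resting 1-second segments.
#' @param n_ch,amplitude_cap Detection rule parameters, see
#'   [calibrate_detection()].
#' @return Object of class `"artefact_models"` with `detection`,
#'   `ref_thresholds`, `bss_cuts`.
#' @export
calibrate_artefact_models <- function(reference_segments, n_ch = 5L,
                                      amplitude_cap = 25) {
  structure(list(
    detection = calibrate_detection(reference_segments, n_ch = n_ch,
                                    amplitude_cap = amplitude_cap),
    ref_thresholds = calibrate_ref_thresholds(reference_segments),
    bss_cuts = calibrate_component_thresholds(reference_segments)),
    class = "artefact_models")
}

#' Apply one artefact-handling method to a detected segment
#'
#' Dispatch helper shared by the stream runner and the benchmark code.
#' `"ignore"` and `"reject"` return the segment untouched (rejection blocks
#' the classifier output downstream instead of altering the data).
#'
#' @param segment Channels x samples matrix.
#' @param detection `"artefact_detection"` for the segment.
#' @param models `"artefact_models"` bundle.
#' @param method One of `"ignore"`, `"reject"`, `"aswtd"`, `"hard"`,
#'   `"soft"`, `"garrote"`, `"sbss"`, `"unv"`, `"ref"`, `"sure"`,
#'   `"amuse"` (`"aswtd"` is the garrote-shrinkage default; the four
#'   shrinkage names select the adaptive algorithm with that function).
#' @return Processed segment.
#' @export
apply_artefact_method <- function(segment, detection, models,
                                  method = "aswtd") {
  switch(method,
    ignore = , reject = segment,
    aswtd = denoise_aswtd(segment, detection, models$detection),
    hard = , soft = , garrote = , sbss =
      denoise_aswtd(segment, detection, models$detection, kind = method),
    unv = denoise_unv(segment, detection),
    ref = denoise_ref(segment, detection, models$ref_thresholds),
    sure = denoise_sure(segment, detection),
    amuse = denoise_bss(segment, detection, models$bss_cuts),
    stop("unknown artefact method '", method, "'"))
}

#' Feature stream of a continuous recording
#'
#' Runs detection (and the chosen artefact handling) on every sliding
#' window, then extracts the 1050 band-power features.  Decision times are
#' the window end times, so decision k of a 128 Hz stream falls at
#' `1 + (k - 1) / 8` seconds.
#'
#' @param eeg Channels x samples matrix, montage rownames.
#' @param models `"artefact_models"` bundle.
#' @param method Artefact handling method, see [apply_artefact_method()].
#' @param fs Sampling rate (Hz).
#' @return List: `x` (segments x 1050 feature matrix), `times` (window end
#'   times, s), `flagged` (logical, artefact detected).
#' @export
feature_stream <- function(eeg, models, method = "ignore", fs = 128) {
  starts <- segment_starts(eeg)
  x <- matrix(0, length(starts), 1050L)
  flagged <- logical(length(starts))
  for (k in seq_along(starts)) {
    seg <- eeg[, starts[k] + 0:127, drop = FALSE]
    det <- detect_segment(seg, models$detection)
    flagged[k] <- !det$clean
    seg <- apply_artefact_method(seg, det, models, method)
    x[k, ] <- psd_features(bipolar_derive(seg), fs = fs)
  }
  list(x = x, times = (starts - 1L + 128L) / fs, flagged = flagged)
}

# IC/NC labels for training: a window is intentional control when its end
# time lies in [event + 0.5, event + 1.0] (it then covers at least half of
# the 1-second post-event signature and any activation it produces falls
# inside the TP scoring window).  Windows partially overlapping a signature
# are ambiguous and are excluded from training.
.label_segments <- function(times, events) {
  ic <- amb <- rep(FALSE, length(times))
  for (e in events) {
    ic <- ic | (times >= e + 0.5 & times <= e + 1.0)
    amb <- amb | (times > e - 0.5 & times < e + 1.5)
  }
  list(y = as.integer(ic), keep = ic | !amb)
}

#' Train the self-paced BCI classifier
#'
#' Features are extracted from the training sessions with the chosen
#' artefact handling; stepwise selection picks the discriminative features;
#' an LDA is fitted on the selected set; and the decision threshold is swept
#' on held-out validation data (the last `val_seconds` of the last training
#' session, mirroring the last-minute-of-last-training-session convention)
#' to the largest TPR subject to `tnfpr <= tnfpr_target` under the full
#' decision chain (moving average, rejection blocking, debounce, dwell
#' gating).
#'
#' @param sessions A `"bci_session"` or list of them (training data).
#' @param models `"artefact_models"` calibrated on resting reference data.
#' @param method Artefact handling method used throughout.
#' @param val_seconds Validation span at the end of the last session (s).
#' @param tnfpr_target Maximum tolerated false positives per minute.
#' @param t_db Debounce period (decision samples).
#' @param max_features Stepwise selection cap.
#' @return Object of class `"bci_model"`: `selected`, `lda`, `direction`,
#'   `threshold`, `method`, `models`, `t_db`, `validation` (metrics at the
#'   chosen threshold).
#' @export
bci_train <- function(sessions, models, method = "ignore", val_seconds = 60,
                      tnfpr_target = 2, t_db = 8L, max_features = 140L) {
  if (inherits(sessions, "bci_session")) sessions <- list(sessions)
  streams <- lapply(sessions, function(s)
    c(feature_stream(s$eeg, models, method, s$fs), list(session = s)))
  last <- streams[[length(streams)]]
  val_cut <- max(last$times) - val_seconds
  val_idx <- last$times > val_cut

  x <- do.call(rbind, c(lapply(streams[-length(streams)], `[[`, "x"),
                        list(last$x[!val_idx, , drop = FALSE])))
  lab <- do.call(c, lapply(seq_along(streams), function(i) {
    tt <- streams[[i]]$times
    if (i == length(streams)) tt <- tt[!val_idx]
    l <- .label_segments(tt, streams[[i]]$session$events)
    ifelse(l$keep, l$y, NA_integer_)
  }))
  keep <- !is.na(lab)
  selected <- stepwise_select(x[keep, , drop = FALSE], lab[keep],
                              max_features = max_features)
  if (!length(selected)) stop("stepwise selection found no usable feature")
  fit <- MASS::lda(x[keep, selected, drop = FALSE],
                   grouping = factor(lab[keep], levels = c(0, 1)))
  # orient scores so that larger means intentional control
  proj <- as.numeric(fit$means %*% fit$scaling)
  direction <- if (proj[2L] >= proj[1L]) 1 else -1

  score <- function(xmat) direction *
    as.numeric(xmat[, selected, drop = FALSE] %*% fit$scaling -
               sum(colMeans(fit$means) * fit$scaling))

  vs <- score(last$x[val_idx, , drop = FALSE])
  vt <- last$times[val_idx]
  vflag <- last$flagged[val_idx]
  vsess <- last$session
  vevents <- vsess$events[vsess$events > val_cut]
  threshold <- .sweep_threshold(vs, vt, vflag, vsess, vevents, method,
                                tnfpr_target, t_db)
  dec <- .decide(vs, vt, vflag, vsess, method, threshold$threshold, t_db)
  structure(list(selected = selected, lda = fit, direction = direction,
                 threshold = threshold$threshold, method = method,
                 models = models, t_db = t_db, score_fun = score,
                 validation = score_session(dec, vt, vevents)),
            class = "bci_model")
}

.decide <- function(scores, times, flagged, session, method, threshold,
                    t_db) {
  block <- if (method == "reject") flagged else NULL
  dec <- classify_stream(scores, threshold, t_db = t_db, block = block)
  dwell_gate(dec, times, session$gaze, session$dwell_time)
}

# Threshold sweep: candidates are quantiles of the validation scores; the
# largest TPR with TNFPR within target wins.  The validation TPR is coarse
# (few events), so ties are common; taking the median qualifying threshold
# balances test-set sensitivity against false-positive margin.
.sweep_threshold <- function(scores, times, flagged, session, events,
                             method, tnfpr_target, t_db, n_cand = 200L) {
  cand <- unique(stats::quantile(scores, probs = seq(0, 1, length.out = n_cand),
                                 names = FALSE, type = 1))
  ok_th <- ok_tpr <- numeric(0)
  for (th in cand) {
    dec <- .decide(scores, times, flagged, session, method, th, t_db)
    sc <- score_session(dec, times, events)
    if (!is.na(sc$tpr) && sc$tnfpr <= tnfpr_target) {
      ok_th <- c(ok_th, th); ok_tpr <- c(ok_tpr, sc$tpr)
    }
  }
  if (!length(ok_th)) return(list(threshold = Inf, tpr = NA_real_))
  top <- ok_th[ok_tpr == max(ok_tpr)]
  list(threshold = stats::median(top), tpr = max(ok_tpr))
}

#' Best operating point of a trained model on a session
#'
#' Sweeps the decision threshold over the session's score stream (full
#' decision chain: moving average, rejection blocking, debounce, dwell
#' gating) and returns the largest true positive rate attainable while the
#' time-normalised false positive rate stays within `tnfpr_target` — the
#' fixed-false-positive-budget statistic used to compare artefact handling
#' methods.
#'
#' @param model A `"bci_model"` from [bci_train()].
#' @param session A `"bci_session"`.
#' @param tnfpr_target Maximum tolerated false positives per minute.
#' @return List: `tpr` (percent), `threshold`.
#' @export
bci_operating_point <- function(model, session, tnfpr_target = 2) {
  st <- feature_stream(session$eeg, model$models, model$method, session$fs)
  scores <- model$score_fun(st$x)
  .sweep_threshold(scores, st$times, st$flagged, session, session$events,
                   model$method, tnfpr_target, model$t_db)
}

#' Run a trained BCI model over a test session
#'
#' Pseudo-online evaluation: the continuous test recording is processed
#' segment by segment exactly as during training (same artefact handling),
#' scored, smoothed, thresholded, debounced and dwell-gated; the resulting
#' decision stream is scored against the session's switch events.
#'
#' @param model A `"bci_model"` from [bci_train()].
#' @param session A `"bci_session"` test session.
#' @return List: `decisions` (0/1), `times`, `scores`, `flagged`, `metrics`
#'   (from [score_session()]).
#' @export
bci_test <- function(model, session) {
  st <- feature_stream(session$eeg, model$models, model$method, session$fs)
  scores <- model$score_fun(st$x)
  dec <- .decide(scores, st$times, st$flagged, session, model$method,
                 model$threshold, model$t_db)
  list(decisions = dec, times = st$times, scores = scores,
       flagged = st$flagged,
       metrics = score_session(dec, st$times, session$events))
}
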