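# Delimited-text I/O for continuous EEG.  Recordings travel as plain CSV:
# one row per sample, one named column per channel, values in microvolts.
# (No EDF reader ships with this package; export EDF recordings to CSV
# upstream.)

#' Read a continuous EEG recording from CSV
#'
#' @param path CSV file: header row of channel names, one sample per row.
#' @param fs Sampling rate to attach (Hz).
#' @return Channels x samples numeric matrix with an `fs` attribute.
#' @export
read_eeg_csv <- function(path, fs = 128) {
  d <- utils::read.csv(path, check.names = FALSE)
  x <- t(as.matrix(d))
  storage.mode(x) <- "double"
  attr(x, "fs") <- fs
  x
}

#' Write a continuous EEG recording to CSV
#'
#' @param eeg Channels x samples matrix with channel rownames.
#' @param path Output file.
#' @export
write_eeg_csv <- function(eeg, path) {
  utils::write.csv(as.data.frame(t(eeg)), path, row.names = FALSE)
}

#' Cut a continuous recording into 1-second calibration segments
#'
#' Non-overlapping windows of `fs` samples, as used for threshold
#' calibration from a resting reference recording.
#'
#' @param eeg Channels x samples matrix.
#' @param fs Samples per segment.
#' @return List of channels x fs matrices.
#' @export
cut_segments <- function(eeg, fs = 128) {
  k <- floor(ncol(eeg) / fs)
  if (k < 1L) stop("recording shorter than one segment")
  lapply(seq_len(k), function(i) eeg[, (i - 1L) * fs + seq_len(fs),
                                     drop = FALSE])
}

#' Denoise a continuous recording
#'
#' Detects and removes artefacts over consecutive non-overlapping 1-second
#' segments (the overlapped 8/s segmentation is only needed when feeding
#' the classifier; for producing a cleaned recording each second is
#' processed once).
#'
#' @param eeg Channels x samples matrix.
#' @param models `"artefact_models"` from [calibrate_artefact_models()].
#' @param method Artefact removal method, see [apply_artefact_method()].
#' @param fs Sampling rate (Hz).
#' @return List: `eeg` (denoised matrix, same shape up to trailing partial
#'   second), `flags` (data frame per segment: index, low_freq, high_freq,
#'   triggering_rule).
#' @export
denoise_recording <- function(eeg, models, method = "aswtd", fs = 128) {
  segs <- cut_segments(eeg, fs)
  out <- eeg[, seq_len(length(segs) * fs), drop = FALSE]
  flags <- vector("list", length(segs))
  for (i in seq_along(segs)) {
    det <- detect_segment(segs[[i]], models$detection)
    out[, (i - 1L) * fs + seq_len(fs)] <-
      apply_artefact_method(segs[[i]], det, models, method)
    flags[[i]] <- data.frame(segment = i, low_freq = det$low_freq,
                             high_freq = det$high_freq,
                             triggering_rule = det$triggering_rule)
  }
  list(eeg = out, flags = do.call(rbind, flags))
}
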