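#' Standardize a recording before feature extraction
#'
#' Removes DC offset, optionally resamples to the nominal analysis rate
#' (10 kHz), trims recordings longer than 1 s to the contiguous 1 s window
#' of maximal RMS energy, and peak-normalizes to 0.9 full scale.
#'
#' @param rec A [voice_recording()].
#' @param target_rate_hz Analysis rate; inputs at other rates are
#'   resampled. `NULL` keeps the input rate.
#' @param trim_s Maximal retained duration in seconds (`NULL` disables
#'   trimming).
#' @return A preprocessed `voice_recording`.
#' @export
preprocess <- function(rec, target_rate_hz = 10000, trim_s = 1.0) {
  stopifnot(inherits(rec, "voice_recording"))
  x <- rec$samples - mean(rec$samples)
  if (max(abs(x)) < 1e-12) stop("silent recording")
  fs <- rec$sample_rate_hz
  if (!is.null(target_rate_hz) && fs != target_rate_hz) {
    x <- as.numeric(signal::resample(x, p = target_rate_hz, q = fs))
    fs <- target_rate_hz
  }
  if (!is.null(trim_s)) {
    n_w <- round(trim_s * fs)
    if (length(x) > n_w) {
      energy <- cumsum(x^2)
      win <- energy[n_w:length(x)] - c(0, energy)[1:(length(x) - n_w + 1)]
      start <- which.max(win)
      x <- x[start:(start + n_w - 1)]
    }
  }
  x <- x / max(abs(x)) * 0.9
  voice_recording(x, sample_rate_hz = fs, bit_depth = rec$bit_depth,
                  id = rec$id)
}

#' Slice a signal into fixed-length frames
#'
#' @param x Numeric signal.
#' @param frame_len Frame length in samples.
#' @param hop Hop size in samples.
#' @return A `frame_len` x `n_frames` matrix (columns are frames).
#' @keywords internal
frame_signal <- function(x, frame_len, hop) {
  if (frame_len > length(x)) stop("frame longer than signal")
  if (hop <= 0) stop("hop must be positive")
  starts <- seq(1, length(x) - frame_len + 1, by = hop)
  vapply(starts, function(s) x[s:(s + frame_len - 1)], numeric(frame_len))
}
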