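# The four sustained-vowel parameters:
#   A1 - mean zero-crossing count per sample per frame,
#   A2 - mean absolute deviation of local peak/valley amplitudes,
#   A3 - mean absolute deviation of the F1/F2 formant tracks (Hz),
#   A4 - fraction of spectral power above the 3 kHz end frequency.

#' Acoustic analysis settings
#'
#' @param frame_ms Frame length in ms for framing-based features.
#' @param hop_ms Hop between frames in ms.
#' @param end_freq_hz End frequency for the spectral energy ratio (A4).
#' @param lpc_order LPC order for formant estimation; `NULL` means the
#'   standard `2 + sample_rate_hz / 1000` (12 at 10 kHz).
#' @param preemphasis Pre-emphasis coefficient applied before LPC.
#' @param bw_max_hz Maximal accepted formant bandwidth.
#' @param f_min_hz,f_max_hz Accepted formant frequency range.
#' @return A list of settings.
#' @export
acoustic_config <- function(frame_ms = 25, hop_ms = 10, end_freq_hz = 3000,
                            lpc_order = NULL, preemphasis = 0.97,
                            bw_max_hz = 400, f_min_hz = 90, f_max_hz = 4000) {
  list(frame_ms = frame_ms, hop_ms = hop_ms, end_freq_hz = end_freq_hz,
       lpc_order = lpc_order, preemphasis = preemphasis,
       bw_max_hz = bw_max_hz, f_min_hz = f_min_hz, f_max_hz = f_max_hz)
}

mean_abs_dev <- function(v) mean(abs(v - mean(v)))

# 3.4 kHz low-pass (cached Butterworth) isolating the voiced band used by
# the temporal measures and the formant fit; a no-op at low sample rates
phonation_band <- function(x, fs) {
  if (fs / 2 <= 3600) return(x)
  key <- paste0("butter_lp_phonation|", fs)
  lp <- .fv_cache[[key]]
  if (is.null(lp)) {
    lp <- signal::butter(6, 3400 / (fs / 2), type = "low")
    .fv_cache[[key]] <- lp
  }
  as.numeric(.iir_filter_cpp(x, lp$b, lp$a))
}

# Sign vector with exact zeros inheriting the previous (or, leading, the
# first following) non-zero sign, so a touch of zero is never counted as
# two crossings.
filled_sign <- function(x) {
  s <- sign(x)
  nz <- which(s != 0)
  if (length(nz) == 0) return(s)
  idx <- cumsum(s != 0)
  idx[idx == 0] <- 1
  s[] <- s[nz][idx]
  s
}

#' Average zero-crossing rate (A1)
#'
#' Counts sign changes between consecutive samples within each frame and
#' divides by the frame length in samples; A1 is the mean over frames.
#'
#' @param rec A (preprocessed) [voice_recording()].
#' @param config [acoustic_config()].
#' @return A1, in crossings per sample (dimensionless, in \[0, 1\]).
#' @export
compute_a1 <- function(rec, config = acoustic_config()) {
  fs <- rec$sample_rate_hz
  frame_len <- round(config$frame_ms / 1000 * fs)
  hop <- round(config$hop_ms / 1000 * fs)
  s <- filled_sign(rec$samples)
  if (frame_len > length(s)) stop("frame longer than signal")
  # crossing indicator between consecutive samples; per-frame totals via
  # a cumulative sum over each frame's frame_len - 1 sample pairs
  change <- cumsum(c(0, s[-1] != s[-length(s)]))
  starts <- seq(1, length(s) - frame_len + 1, by = hop)
  crossings <- change[starts + frame_len - 1] - change[starts]
  mean(crossings / frame_len)
}

# Fundamental-frequency estimate by the autocorrelation method (FFT-based),
# searched over the human phonation range.
estimate_f0 <- function(x, fs, f_min = 60, f_max = 400) {
  # 0.4 s is ample for a sustained vowel; keeps the FFT small
  if (length(x) > 4096) x <- x[seq_len(4096)]
  n <- length(x)
  m <- nextn(2 * n)
  sp <- fft(c(x - mean(x), numeric(m - n)))
  ac <- Re(fft(sp * Conj(sp), inverse = TRUE))[1:n]
  lag_min <- max(2, floor(fs / f_max))
  lag_max <- min(n - 1, ceiling(fs / f_min))
  if (lag_max <= lag_min) return(NA_real_)
  window <- ac[(lag_min + 1):(lag_max + 1)]
  best <- which.max(window) + lag_min
  if (ac[best + 1] < 0.2 * ac[1]) return(NA_real_)
  fs / best
}

#' Peak/valley amplitude variation (A2)
#'
#' Detects local maxima (peaks) and minima (valleys) over the whole
#' utterance with a minimum inter-extremum spacing of half the estimated
#' fundamental period, then averages the mean absolute deviation of peak
#' amplitudes and of valley amplitudes:
#' `A2 = (MAD(peaks) + MAD(valleys)) / 2`, in full-scale amplitude units.
#'
#' @inheritParams compute_a1
#' @return A2 (>= 0).
#' @export
compute_a2 <- function(rec, config = acoustic_config()) {
  fs <- rec$sample_rate_hz
  # peaks and valleys of the phonation waveform: superimposed aspiration
  # noise (> 3 kHz, the spectral ratio's band) is removed first so A2
  # reflects cycle-level amplitude instability
  x <- phonation_band(rec$samples, fs)
  f0 <- estimate_f0(x, fs)
  if (is.na(f0)) f0 <- 150 # non-periodic fallback spacing
  min_dist <- max(1L, as.integer(round(0.5 * fs / f0)))
  # drop extrema of partial cycles at the signal edges
  interior <- function(idx) idx[idx > min_dist & idx <= length(x) - min_dist]
  peaks <- x[interior(.peaks_min_dist_cpp(x, min_dist))]
  valleys <- x[interior(.peaks_min_dist_cpp(-x, min_dist))]
  if (length(peaks) < 4 || length(valleys) < 4) {
    stop("too few extrema for A2 (non-oscillating signal)")
  }
  (mean_abs_dev(peaks) + mean_abs_dev(valleys)) / 2
}

#' Estimate F1/F2 of a single frame by autocorrelation LPC
#'
#' Applies pre-emphasis and a Hamming window, fits linear-prediction
#' coefficients by Levinson-Durbin, converts the upper-half-plane roots of
#' the prediction polynomial to (frequency, bandwidth) pairs, keeps
#' candidates with bandwidth below `bw_max_hz` and frequency inside
#' `[f_min_hz, f_max_hz]`, and returns the two lowest surviving
#' frequencies.
#'
#' @param frame Numeric vector, one analysis frame.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param config [acoustic_config()].
#' @return `list(f1_hz, f2_hz, valid)`; `valid = FALSE` (with `NA`
#'   frequencies) when fewer than two candidates survive or the
#'   autocorrelation system is degenerate.
#' @export
estimate_formants <- function(frame, sample_rate_hz,
                              config = acoustic_config()) {
  m <- prep_lpc_frames(matrix(frame, ncol = 1), config)
  order <- lpc_order_for(sample_rate_hz, config)
  res <- .lpc_formants_cpp(m, order, sample_rate_hz, config$bw_max_hz,
                           config$f_min_hz, config$f_max_hz)
  list(f1_hz = res[1, 1], f2_hz = res[1, 2], valid = res[1, 3] == 1)
}

lpc_order_for <- function(fs, config) {
  if (!is.null(config$lpc_order)) return(as.integer(config$lpc_order))
  as.integer(2 + fs / 1000)
}

# pre-emphasis across the frame, then Hamming window (columns = frames)
prep_lpc_frames <- function(frames, config) {
  n <- nrow(frames)
  pre <- frames - config$preemphasis *
    rbind(frames[1, , drop = FALSE], frames[-n, , drop = FALSE])
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  pre * w
}

#' Track F1/F2 over an utterance
#'
#' Frames the recording (default 25 ms frames, 10 ms hop) and runs
#' [estimate_formants()] per frame.
#'
#' @inheritParams compute_a1
#' @return A data.frame with columns `frame`, `f1_hz`, `f2_hz`, `valid`.
#' @export
formant_track <- function(rec, config = acoustic_config()) {
  fs <- rec$sample_rate_hz
  frame_len <- round(config$frame_ms / 1000 * fs)
  hop <- round(config$hop_ms / 1000 * fs)
  # restrict the analysis band: F1-F3 live well below 3.4 kHz, and
  # broadband energy above it (aspiration noise) only distorts the pole fit
  x <- phonation_band(rec$samples, fs)
  frames <- frame_signal(x, frame_len, hop)
  m <- prep_lpc_frames(frames, config)
  res <- .lpc_formants_cpp(m, lpc_order_for(fs, config), fs,
                           config$bw_max_hz, config$f_min_hz, config$f_max_hz)
  valid <- res[, 3] == 1
  # gate stray frames (e.g. a noise-band pole standing in for a dropped
  # F2): frames far from the track median are not credible formants
  if (sum(valid) >= 5) {
    med1 <- stats::median(res[valid, 1])
    med2 <- stats::median(res[valid, 2])
    valid <- valid & abs(res[, 1] - med1) < 600 & abs(res[, 2] - med2) < 600
  }
  data.frame(frame = seq_len(nrow(res)), f1_hz = res[, 1], f2_hz = res[, 2],
             valid = valid)
}

#' Formant variation (A3)
#'
#' Mean absolute deviation of the F1 track plus that of the F2 track,
#' halved, over valid frames: resonance instability in Hz.
#'
#' @param track Output of [formant_track()].
#' @return A3 in Hz.
#' @export
compute_a3 <- function(track) {
  ok <- track$valid & is.finite(track$f1_hz) & is.finite(track$f2_hz)
  if (sum(ok) < 5) stop("too few valid formant frames for A3")
  (mean_abs_dev(track$f1_hz[ok]) + mean_abs_dev(track$f2_hz[ok])) / 2
}

#' High-frequency spectral energy ratio (A4)
#'
#' Welch-averaged power spectrum (25 ms Hamming segments, 50% overlap, DC
#' bin excluded); A4 is the power above the end frequency (3 kHz) divided
#' by the total power.
#'
#' @inheritParams compute_a1
#' @return A4 in \[0, 1\].
#' @export
compute_a4 <- function(rec, config = acoustic_config()) {
  fs <- rec$sample_rate_hz
  if (fs <= 2 * config$end_freq_hz) {
    stop("sample rate too low: no band above the end frequency")
  }
  seg_len <- round(0.025 * fs)
  hop <- max(1L, seg_len %/% 2L)
  frames <- frame_signal(rec$samples, seg_len, hop)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1))
  pxx <- rowSums(Mod(mvfft(frames * w))^2)
  half <- 2:(seg_len %/% 2 + 1) # one-sided, DC excluded
  freqs <- (half - 1) * fs / seg_len
  p <- pxx[half]
  sum(p[freqs > config$end_freq_hz]) / sum(p)
}

#' Extract all four acoustic features from one recording
#'
#' Runs [preprocess()] and computes A1, A2, A3 (via the formant track) and
#' A4. Per-feature failures are reported as `NA` with a reason instead of
#' an error, so one bad recording never aborts a batch.
#'
#' @param rec A [voice_recording()] or a path to a WAV file.
#' @param config [acoustic_config()].
#' @param preprocessed Set `TRUE` when `rec` is already preprocessed.
#' @return One-row data.frame: `id`, `a1`..`a4`, per-feature `*_ok` flags,
#'   and a `reason` string (empty when everything succeeded).
#' @export
extract_features <- function(rec, config = acoustic_config(),
                             preprocessed = FALSE) {
  if (is.character(rec)) rec <- read_wav(rec)
  id <- rec$id
  reasons <- character(0)
  vals <- c(a1 = NA_real_, a2 = NA_real_, a3 = NA_real_, a4 = NA_real_)
  pp <- tryCatch(if (preprocessed) rec else preprocess(rec),
                 error = function(e) e)
  if (inherits(pp, "error")) {
    reasons <- conditionMessage(pp)
  } else {
    grab <- function(feature, expr) {
      v <- tryCatch(expr, error = function(e) {
        reasons <<- c(reasons, paste0(feature, ": ", conditionMessage(e)))
        NA_real_
      })
      vals[feature] <<- v
    }
    grab("a1", compute_a1(pp, config))
    grab("a2", compute_a2(pp, config))
    grab("a3", compute_a3(formant_track(pp, config)))
    grab("a4", compute_a4(pp, config))
  }
  data.frame(id = id, a1 = vals[["a1"]], a2 = vals[["a2"]],
             a3 = vals[["a3"]], a4 = vals[["a4"]],
             a1_ok = is.finite(vals[["a1"]]), a2_ok = is.finite(vals[["a2"]]),
             a3_ok = is.finite(vals[["a3"]]), a4_ok = is.finite(vals[["a4"]]),
             reason = paste(reasons, collapse = "; "),
             stringsAsFactors = FALSE)
}

#' Extract features for a batch of recordings
#'
#' @param recs List of [voice_recording()]s, a character vector of WAV
#'   paths, or a directory containing WAV files.
#' @param config [acoustic_config()].
#' @return A data.frame with one row per recording (see
#'   [extract_features()]).
#' @export
extract_features_batch <- function(recs, config = acoustic_config()) {
  if (is.character(recs) && length(recs) == 1 && dir.exists(recs)) {
    recs <- list.files(recs, pattern = "\\.[Ww][Aa][Vv]$", full.names = TRUE)
  }
  rows <- lapply(recs, function(r) {
    tryCatch(extract_features(r, config), error = function(e) {
      data.frame(id = if (is.character(r)) basename(r) else r$id,
                 a1 = NA_real_, a2 = NA_real_, a3 = NA_real_, a4 = NA_real_,
                 a1_ok = FALSE, a2_ok = FALSE, a3_ok = FALSE, a4_ok = FALSE,
                 reason = conditionMessage(e), stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}
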