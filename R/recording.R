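#' Construct a voice recording
#'
#' A mono sampled waveform with rate and bit-depth metadata; the container
#' every acoustic operation consumes.
#'
#' @param samples Numeric vector of amplitudes, nominally full-scale
#'   \[-1, 1\].
#' @param sample_rate_hz Sampling rate in Hz.
#' @param bit_depth Quantization depth of the source (metadata only;
#'   samples are stored as doubles).
#' @param id Identifier string.
#' @return An object of class `voice_recording`.
#' @export
voice_recording <- function(samples, sample_rate_hz, bit_depth = 16L,
                            id = "recording") {
  samples <- as.numeric(samples)
  if (sample_rate_hz <= 0) stop("sample_rate_hz must be positive")
  if (any(!is.finite(samples))) stop("samples must be finite")
  structure(
    list(samples = samples, sample_rate_hz = sample_rate_hz,
         bit_depth = as.integer(bit_depth), id = as.character(id)),
    class = "voice_recording"
  )
}

#' @export
print.voice_recording <- function(x, ...) {
  cat(sprintf("<voice_recording '%s': %d samples @ %g Hz (%.3f s), %d-bit>\n",
              x$id, length(x$samples), x$sample_rate_hz,
              length(x$samples) / x$sample_rate_hz, x$bit_depth))
  invisible(x)
}

#' @export
length.voice_recording <- function(x) length(x$samples)

duration_s <- function(rec) length(rec$samples) / rec$sample_rate_hz
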