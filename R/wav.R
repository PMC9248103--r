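# Minimal RIFF WAV support: PCM mono, 8/16/24-bit. Chunks other than
# "fmt " and "data" are skipped; stereo input is rejected.

#' Read a mono PCM WAV file
#'
#' Decodes a RIFF/WAVE file (PCM, mono, 8/16/24-bit) into a
#' [voice_recording()]. Samples are scaled to full-scale \[-1, 1\].
#'
#' @param path Path to a `.wav` file.
#' @param id Recording identifier; defaults to the file name without
#'   extension.
#' @return A `voice_recording`.
#' @export
read_wav <- function(path, id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    tag <- readChar(con, 4, useBytes = TRUE)
    if (length(tag) == 0 || nchar(tag) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(tag, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        n_channels = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        sample_rate = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(tag, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk: ", path)
  if (fmt$audio_format != 1) stop("only PCM WAV supported (format ",
                                  fmt$audio_format, ")")
  if (fmt$n_channels != 1) stop("stereo recordings are not supported; ",
                                "supply mono WAV files")
  bits <- fmt$bits
  x <- switch(as.character(bits),
    "8" = {
      u <- as.integer(data_raw) # unsigned bytes
      (u - 128) / 128
    },
    "16" = {
      v <- readBin(data_raw, "integer", length(data_raw) %/% 2, 2,
                   signed = TRUE, endian = "little")
      v / 32768
    },
    "24" = {
      n <- length(data_raw) %/% 3
      b <- matrix(as.integer(data_raw[seq_len(n * 3)]), nrow = 3)
      v <- b[1, ] + b[2, ] * 256 + b[3, ] * 65536
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    stop("unsupported bit depth: ", bits)
  )
  if (is.null(id)) id <- sub("\\.[Ww][Aa][Vv]$", "", basename(path))
  voice_recording(x, sample_rate_hz = fmt$sample_rate, bit_depth = bits,
                  id = id)
}

#' Write a voice recording as 16-bit PCM mono WAV
#'
#' @param rec A `voice_recording` (samples in \[-1, 1\]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "voice_recording"))
  x <- pmax(-1, pmin(1, rec$samples))
  v <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
  n_bytes <- length(v) * 2L
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")  # PCM
  writeBin(1L, con, 2, endian = "little")  # mono
  sr <- as.integer(rec$sample_rate_hz)
  writeBin(sr, con, 4, endian = "little")
  writeBin(as.integer(sr * 2L), con, 4, endian = "little") # byte rate
  writeBin(2L, con, 2, endian = "little")  # block align
  writeBin(16L, con, 2, endian = "little") # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4, endian = "little")
  writeBin(v, con, 2, endian = "little")
  invisible(path)
}
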