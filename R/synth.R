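# Source-filter synthesis of a sustained /a/: glottal pulse train with
# per-cycle jitter/shimmer, two one-pole low-pass sections for spectral
# tilt, a cascade of second-order formant resonators (F1/F2 optionally
# random-walking), and additive high-pass noise.

#' Specify a synthetic sustained vowel
#'
#' Bundles and validates every knob of the vowel synthesizer. Defaults give
#' a clean male-like /a/ at the pipeline's nominal 10 kHz rate.
#'
#' @param duration_s Duration in seconds (> 0).
#' @param f0_hz Fundamental frequency in Hz.
#' @param jitter_rel Cycle-to-cycle relative SD of the fundamental period
#'   (dimensionless, >= 0).
#' @param shimmer_rel Cycle-to-cycle relative SD of pulse amplitude
#'   (dimensionless, >= 0).
#' @param formants List of `c(center_hz, bandwidth_hz)` pairs for F1..F3,
#'   centers strictly increasing and below Nyquist.
#' @param formant_drift_hz Per-frame (10 ms) SD of the random walk applied
#'   to the F1 and F2 centers, reflected at +/- 20% of the center.
#' @param noise_hf_rel Power of added high-pass (> 3 kHz) noise relative to
#'   the vowel's power (>= 0).
#' @param sample_rate_hz Sampling rate in Hz.
#' @param seed Integer seed making the synthesis deterministic.
#' @return An object of class `vowel_spec`.
#' @export
#' @examples
#' spec <- vowel_spec(f0_hz = 120, seed = 1)
#' rec <- synthesize_vowel(spec)
vowel_spec <- function(duration_s = 1.0, f0_hz = 120,
                       jitter_rel = 0.005, shimmer_rel = 0.03,
                       formants = list(c(700, 80), c(1200, 90), c(2600, 120)),
                       formant_drift_hz = 5, noise_hf_rel = 0.001,
                       sample_rate_hz = 10000, seed = 1L) {
  spec <- structure(
    list(duration_s = duration_s, f0_hz = f0_hz, jitter_rel = jitter_rel,
         shimmer_rel = shimmer_rel, formants = formants,
         formant_drift_hz = formant_drift_hz, noise_hf_rel = noise_hf_rel,
         sample_rate_hz = sample_rate_hz, seed = as.integer(seed)),
    class = "vowel_spec"
  )
  validate_vowel_spec(spec)
  spec
}

validate_vowel_spec <- function(spec) {
  chk <- function(ok, field, why) {
    if (!isTRUE(ok)) stop("invalid vowel_spec field '", field, "': ", why,
                          call. = FALSE)
  }
  chk(is.numeric(spec$duration_s) && spec$duration_s > 0,
      "duration_s", "must be > 0")
  nyq <- spec$sample_rate_hz / 2
  chk(is.numeric(spec$sample_rate_hz) && spec$sample_rate_hz > 0,
      "sample_rate_hz", "must be > 0")
  chk(spec$f0_hz > 0 && spec$f0_hz < nyq,
      "f0_hz", "must lie in (0, sample_rate_hz/2)")
  chk(spec$jitter_rel >= 0, "jitter_rel", "must be >= 0")
  chk(spec$shimmer_rel >= 0, "shimmer_rel", "must be >= 0")
  chk(spec$formant_drift_hz >= 0, "formant_drift_hz", "must be >= 0")
  chk(spec$noise_hf_rel >= 0, "noise_hf_rel", "must be >= 0")
  centers <- vapply(spec$formants, `[`, numeric(1), 1)
  bws <- vapply(spec$formants, `[`, numeric(1), 2)
  chk(length(centers) >= 1 && all(diff(centers) > 0),
      "formants", "centers must be strictly increasing")
  chk(all(centers > 0 & centers < nyq),
      "formants", "centers must lie in (0, sample_rate_hz/2)")
  chk(all(bws > 0), "formants", "bandwidths must be > 0")
  invisible(spec)
}

# Spectral tilt of the glottal source: two identical one-pole low-pass
# sections (total -12 dB/oct well above the corner), pole at 0.95.
TILT_POLE <- 0.95

#' A typical elderly sustained /a/ specification
#'
#' The cohort generator's operating point: moderate jitter, shimmer,
#' formant drift and aspiration noise representative of an older
#' speaker's held vowel.
#'
#' @param ... Overrides passed to [vowel_spec()].
#' @return A [vowel_spec()].
#' @export
elderly_vowel_spec <- function(...) {
  args <- list(...)
  defaults <- list(f0_hz = 140, jitter_rel = 0.005, shimmer_rel = 0.06,
                   formant_drift_hz = 3, noise_hf_rel = 0.05, seed = 1L)
  do.call(vowel_spec, utils::modifyList(defaults, args))
}

# Glottal pulse train with multiplicative jitter/shimmer, perturbations
# clipped at +/- 3 SD to avoid period collapse.
glottal_source <- function(n, f0_hz, jitter_rel, shimmer_rel, fs) {
  base_period <- fs / f0_hz
  n_cycles <- ceiling(n / base_period) + 4
  clip3 <- function(z) pmax(-3, pmin(3, z))
  periods <- base_period * (1 + jitter_rel * clip3(rnorm(n_cycles)))
  periods <- pmax(periods, 2)
  amps <- 1 + shimmer_rel * clip3(rnorm(n_cycles))
  amps <- pmax(amps, 0.05)
  onsets <- round(cumsum(c(1, periods)))
  keep <- onsets <= n
  x <- numeric(n)
  x[onsets[keep]] <- amps[seq_len(sum(keep))]
  # two one-pole low-pass sections for spectral tilt
  as.numeric(.iir_filter_cpp(x, 1, c(1, -2 * TILT_POLE, TILT_POLE^2)))
}

# Reflected Gaussian random walk for a formant center: one step per 10 ms
# frame, bounded to +/- 20% of the center frequency.
drift_track <- function(center, step_sd, n_frames, innovations = NULL) {
  if (is.null(innovations)) innovations <- rnorm(n_frames)
  lo <- 0.8 * center
  hi <- 1.2 * center
  f <- numeric(n_frames)
  cur <- center
  for (t in seq_len(n_frames)) {
    cur <- cur + step_sd * innovations[t]
    if (cur > hi) cur <- 2 * hi - cur
    if (cur < lo) cur <- 2 * lo - cur
    cur <- min(hi, max(lo, cur))
    f[t] <- cur
  }
  f
}

#' Synthesize a sustained vowel recording
#'
#' Source-filter synthesis: a glottal pulse train at `f0_hz` (per-cycle
#' jitter and shimmer, spectral tilt from two one-pole low-pass sections)
#' is passed through a cascade of second-order resonators at the formant
#' centers; the F1/F2 centers follow a reflected random walk updated every
#' 10 ms when `formant_drift_hz > 0`; high-pass (> 3 kHz) Gaussian noise is
#' added at `noise_hf_rel` relative power; the result is peak-normalized to
#' 0.9 full scale. Bit-identical for identical specs (the seed covers all
#' randomness).
#'
#' @param spec A [vowel_spec()].
#' @param id Identifier for the output recording.
#' @return A [voice_recording()] of `round(duration_s * sample_rate_hz)`
#'   samples.
#' @export
synthesize_vowel <- function(spec, id = "synthetic_vowel") {
  validate_vowel_spec(spec)
  fs <- spec$sample_rate_hz
  n <- round(spec$duration_s * fs)
  warm <- round(0.05 * fs) # lead-in absorbing the resonator onset transient
  n_tot <- n + warm
  frame_len <- max(1L, round(0.010 * fs)) # drift update every 10 ms
  n_frames <- ceiling(n_tot / frame_len)

  with_seed(spec$seed, {
    src <- glottal_source(n_tot, spec$f0_hz, spec$jitter_rel,
                          spec$shimmer_rel, fs)
    centers <- vapply(spec$formants, `[`, numeric(1), 1)
    bws <- vapply(spec$formants, `[`, numeric(1), 2)
    k <- length(centers)
    f_tracks <- matrix(rep(centers, each = n_tot), nrow = n_tot, ncol = k)
    if (spec$formant_drift_hz > 0) {
      # F2 carries the full drift; F1 a 30% share - a wandering F1 also
      # modulates cycle amplitudes, which belongs to the shimmer channel
      shares <- c(0.3, 1)
      for (j in seq_len(min(2L, k))) {
        tr <- drift_track(centers[j], shares[j] * spec$formant_drift_hz,
                          n_frames)
        f_tracks[, j] <- rep(tr, each = frame_len)[seq_len(n_tot)]
      }
    }
    y <- .resonator_cascade_cpp(src, f_tracks, bws, fs)
    y <- y[(warm + 1):n_tot]
    y <- y - mean(y) # the tilted pulse train carries DC; drop it
    if (spec$noise_hf_rel > 0) {
      if (fs <= 6000) {
        stop("invalid vowel_spec field 'noise_hf_rel': high-pass noise ",
             "above 3 kHz needs sample_rate_hz > 6000")
      }
      noise <- rnorm(n)
      key <- paste0("butter_hp|", fs)
      hp <- .fv_cache[[key]]
      if (is.null(hp)) {
        hp <- signal::butter(4, 3000 / (fs / 2), type = "high")
        .fv_cache[[key]] <- hp
      }
      noise <- as.numeric(.iir_filter_cpp(noise, hp$b, hp$a))
      target_pow <- spec$noise_hf_rel * mean(y^2)
      noise <- noise * sqrt(target_pow / mean(noise^2))
      y <- y + noise
    }
    y <- y / max(abs(y)) * 0.9
    voice_recording(y, sample_rate_hz = fs, bit_depth = 16L, id = id)
  })
}
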