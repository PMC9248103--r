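# Signal fixtures built in code.

FS <- 10000

# A pure sine with a non-degenerate phase (exact zeros at sample points
# interact with frame boundaries and are not representative input).
make_sine <- function(f0, fs = FS, dur = 1, phase = 0.3, amp = 1,
                      id = paste0("sine", f0)) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  voice_recording(amp * sin(2 * pi * f0 * t + phase), fs, id = id)
}

# 100 Hz carrier whose cycles alternate amplitude 1.0 / 0.8, so peaks
# alternate 1.0/0.8 and valleys mirror at -1.0/-0.8; 50-sample silent
# pads keep every full cycle's extrema away from the signal edges, giving
# 50 peaks (and valleys) of each amplitude. Hand computation: each
# mean absolute deviation is 0.1, so A2 = 0.1.
make_alternating_peak_fixture <- function(fs = FS) {
  cycles <- 100
  spc <- fs / 100 # samples per cycle
  t <- seq_len(cycles * spc) - 1
  amp <- rep(rep(c(1, 0.8), length.out = cycles), each = spc)
  x <- sin(2 * pi * 100 * t / fs) * amp
  voice_recording(c(numeric(50), x, numeric(50)), fs, id = "alt_peaks")
}

# clean deterministic vowel spec (no perturbations)
clean_vowel_spec <- function(f0 = 120, formants = list(c(700, 80),
                                                       c(1200, 90),
                                                       c(2600, 120)),
                             seed = 1) {
  vowel_spec(f0_hz = f0, jitter_rel = 0, shimmer_rel = 0,
             formants = formants, formant_drift_hz = 0, noise_hf_rel = 0,
             seed = seed)
}

# direct sign-change count over the whole signal: the independent oracle
# for the zero-crossing rate
direct_zcr <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  sum(s[-1] != s[-length(s)]) / length(x)
}

# default participant with every criterion negative
robust_participant <- function(id = "p1", sex = "male") {
  participant(id = id, sex = sex, age_years = 70, weight_kg = 65, bmi = 24,
              weight_loss_pct_year = 0, weight_loss_kg_year = 0,
              unintentional = FALSE, exhaustion_answer = FALSE,
              grip_kg = if (sex == "male") 35 else 25,
              gait_speed_m_s = 1.3, cannot_walk = FALSE,
              adl_deterioration = FALSE, chair_stand_unable = FALSE,
              energy_full_answer = TRUE, drug_count = 2)
}
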