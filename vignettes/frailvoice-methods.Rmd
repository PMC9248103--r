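---
title: "Vocal biomarkers of frailty: models, synthesis and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vocal biomarkers of frailty: models, synthesis and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`frailvoice` implements a complete, testable pipeline linking sustained-vowel
acoustics to frailty in older adults: synthesis of /a/ recordings and of a
cohort with a known voice–frailty effect structure, extraction of four
acoustic parameters, frailty scoring on three operational indices, and a
univariate logistic association analysis reported as odds ratios (ORs).
This vignette is the package's methodological record: the models, every
tunable that matters, what the synthetic data do and do not emulate, and
the design decisions taken where more than one defensible choice existed.

## The four acoustic parameters

All analysis operates on mono recordings of a held /a/, nominally 1 s at
10 kHz/16-bit. `preprocess()` removes DC, resamples to 10 kHz when needed,
keeps the contiguous 1 s window of maximal RMS energy of longer takes, and
peak-normalizes to 0.9 full scale. Framing-based measures use 25 ms frames
with a 10 ms hop — a standard speech-analysis compromise between spectral
resolution and stationarity; the frame length is exposed in
`acoustic_config()`.

* **A1 — zero-crossing rate.** Sign changes between consecutive samples,
  counted per frame and divided by the frame length *in samples*, averaged
  over frames; dimensionless in [0, 1]. Exact zero samples inherit the
  previous sign, so a grazing touch of zero never counts twice. For a pure
  sine, A1 ≈ 2·f0/fs; for a vowel it reflects the dominant spectral
  content, and it rises sharply with broadband noise (a real property of
  the measure, visible in the generator's feature couplings below).
* **A2 — peak/valley amplitude variation.** Local maxima and minima are
  detected over the whole utterance with a minimum spacing of half the
  estimated fundamental period (f0 by the autocorrelation method, searched
  in 60–400 Hz), then A2 = ½·[MAD(peaks) + MAD(valleys)], where MAD is the
  *mean absolute deviation* — the ordinary reading of "average deviation";
  a switch to SD would only rescale the measure. Three analysis choices:
  extrema are pooled over the whole utterance (slow amplitude instability
  is then captured, which per-frame pooling would miss); extrema of partial
  cycles within half a period of the signal edges are discarded; and
  amplitudes are read from the ≤ 3.4 kHz phonation band. The last point
  matters: the > 3 kHz aspiration-noise band is exactly what A4 measures,
  and without the band split the noise dominates A2's repeatability
  (measurement SD ≈ 0.02 full scale against a between-speaker spread
  around 0.013).
* **A3 — formant variation.** Per frame, the signal (band-limited to
  3.4 kHz, pre-emphasized at 0.97, Hamming-windowed) is fit by
  autocorrelation-method linear prediction of order 2 + fs/1000 (12 at
  10 kHz, Levinson–Durbin). Upper-half-plane roots of the prediction
  polynomial are converted to (frequency, bandwidth); candidates with
  bandwidth < 400 Hz and frequency in 90–4000 Hz survive, and the two
  lowest are F1 and F2. A frame is invalid if fewer than two survive, or —
  a robustness gate — if its F1/F2 sit more than 600 Hz from the track
  median (under noise a dropped F2 pole is otherwise silently replaced by
  a noise-band pole, which explodes the track). A3 = ½·[MAD(F1) + MAD(F2)]
  over valid frames (≥ 5 required), in Hz. The unweighted mean of the two
  deviations is a convention; a sum would double the scale and halve the
  per-10-Hz OR exponent, nothing more.
* **A4 — spectral energy ratio.** Welch-averaged power spectrum (25 ms
  Hamming segments, 50% overlap, DC bin excluded); A4 is the power above
  the 3 kHz end frequency over total power, in [0, 1]. Welch averaging
  rather than one long FFT reduces the estimate's variance; the end
  frequency is exposed in `acoustic_config()`.

Degenerate inputs are handled explicitly: an all-DC recording errors as
silent; a signal with too few extrema (no phonation) fails A2 with a
reason; in batch mode every per-feature failure becomes an `NA` plus a
reason string, never an abort. One numerical trap worth recording: a
phase-zero sine commensurate with the frame grid puts its exact-zero
crossings on frame boundaries, where the boundary sample pair belongs to
no frame; any generic phase removes the artifact, and the package's sine
oracles use one.

## Frailty scoring

Three indices are scored from raw criterion fields, with the binary
outcome *frail vs robust/pre-frail* used throughout the statistics:

| Index | Items | Frail at |
|---|---|---|
| CHS (Fried phenotype) | unintentional weight loss (≥ 4.5 kg or > 5%/yr), exhaustion, weakness (grip < 28 kg men / < 18 kg women), slowness (gait < 1.0 m/s), ADL deterioration | ≥ 3 of 5 |
| SOF | weight loss > 5%/yr (any intent), unable to chair-stand ×5, not "full of energy" | ≥ 2 of 3 |
| FRAIL | fatigue, resistance (chair stand), ambulation (gait < 1.0 m/s), illness (≥ 8 drugs), weight loss ≥ 5%/yr | 3–5 of 5 |

Boundary conventions follow the items' wording and are all strict or
inclusive as listed (grip exactly at the cutoff is *not* weak; exactly 8
drugs *is* polypharmacy; FRAIL weight loss at exactly 5% counts, SOF's
does not). Participants who cannot perform the walking test count as slow.
All cutoffs are parameters of `frailty_config()`. Missing items count
zero but are listed per assessment, and an assessment is flagged
`incomplete` when the missing items could move it across the frail
threshold — a score of 2/5 with one missing item is reported, but marked.

## The statistical layer

Group screening uses one-way ANOVA of each feature across the binary
frail grouping (for two groups, F is exactly the squared pooled-variance
t statistic, which the tests exploit as an oracle). Associations are
*unadjusted univariate* logistic regressions of frail status on one
feature at a time — deliberately so, matching the descriptive aim; no
covariate adjustment is applied, and the Bonferroni-adjusted p-value
column in the association table is reference-only (no decision uses it).
ORs are reported per *reporting unit*: per 1 unit of A1, per 0.1 of A2
and A4, per 10 Hz of A3, with Wald 95% CIs `exp(b ± 1.96·SE)`.
Probabilities derive from odds as `probability = odds/(1 + odds)`.
Complete separation is caught and refit with a small built-in
Firth-penalized Newton solver, flagged `converged = FALSE` rather than
reported as a silent explosion. Sex-stratified fits (all/male/female ×
4 features × 3 indices = 36 models) mark strata missing an outcome class
as inestimable instead of failing the batch.

## The vowel synthesizer

`synthesize_vowel()` is a source–filter synthesizer:

1. **Glottal source**: an impulse train at f0 whose per-cycle periods and
   amplitudes carry multiplicative Gaussian perturbations (jitter,
   shimmer), clipped at ±3 SD so no period can collapse; spectral tilt
   from two identical one-pole low-pass sections (pole 0.95, about
   −12 dB/oct above the corner) rather than a full LF glottal model —
   enough for realistic harmonic structure.
2. **Vocal tract**: a cascade of second-order resonators at F1–F3
   (defaults 700/1200/2600 Hz, bandwidths 80/90/120 Hz). Sections are
   normalized to unity gain *at the resonance peak*, so a moving center
   changes timbre, not level. F1/F2 centers follow a reflected Gaussian
   random walk stepped every 10 ms and bounded at ±20% of the center;
   F2 carries the full drift SD and F1 a 30% share — a full-strength F1
   walk modulates cycle amplitudes so strongly that the drift channel
   contaminates the shimmer channel (extracted A2–A3 correlation ≈ 0.6;
   with the reduced share ≈ 0.2).
3. **Aspiration noise**: Gaussian noise high-passed above 3 kHz
   (4th-order Butterworth) added at a configured power relative to the
   vowel, then the whole signal is peak-normalized to 0.9.

A 50 ms lead-in is synthesized and discarded so the resonators' onset
transient never reaches the analysis window, and the tilted pulse train's
DC component is removed before the noise power is referenced. Everything
is driven by one seed; identical specs give bit-identical waveforms.

## The synthetic cohort and its effect structure

The generator's task is to make the *extracted* features carry configured
odds ratios against a latent frail status. Two structures connect them:

**Knob calibration.** Each feature has a paired synthesis knob (A1←f0,
A2←shimmer, A3←formant drift, A4←noise power). The knob→feature maps are
measured once per session by sweeping each knob over a grid (three fixed
seeds per point, other knobs at the operating spec), isotonically
smoothed, and inverted. `calibrate_spec_for_features()` exposes the
inverse map and errors with the achievable interval when a target is out
of range. A 200-draw reference pool through the full
calibrate→synthesize→extract chain is also cached; it supplies the
chain's linear response summary (for centering target draws) and the
empirical feature distribution used below.

**Forward effect construction.** Per participant the generator draws
feature targets with *no* group structure, synthesizes and extracts, and
only then assigns frail status from a logistic model **on the extracted
features**; the intercept is solved on the reference pool so the
expected frail fraction equals the configured prevalence. The configured
ORs are *univariate* reporting-scale ORs — the quantity the association
module estimates — so the conditional slopes are obtained from the
configured ones through the reference pool's covariance
(`c = S^{-1} (b ∘ diag S)`, the linear-discriminant identity), restricted
to the features with a non-unit OR: features with no configured effect
would otherwise demand exact cancellation of their correlated
neighbours, which is numerically hopeless when two features are nearly
collinear (broadband noise drives both A1 and A4, r ≈ 0.96 in the pool).
If even the restricted correlation submatrix is ill-conditioned
(condition number ≥ 50) the generator falls back to using the configured
slopes directly and lets univariate fits inherit the confounding, as
real correlated features would. Because status is generated from the
very covariates later fitted, there is no errors-in-variables
attenuation and OR recovery is exact up to sampling noise. An earlier
design that drew status first and shifted feature targets per group
required an error-in-variables correction through the chain's coupling
matrix; that solve proved ill-conditioned and was abandoned. Saturated
configurations (prevalence unreachable for the requested slopes) error
rather than clip.

A configured `sex_interaction` multiplies one feature's OR in one sex,
with per-sex intercepts holding prevalence; stratified fits then see
genuinely different slopes.

**Criterion-field consistency.** Given the assigned status, eight binary
deficits (weight loss, exhaustion, weakness, slowness, ADL, chair-stand,
polypharmacy, low energy) are drawn at a 0.15 background rate; frail
participants receive additional deficits, sampled without replacement per
index, until CHS, SOF *and* FRAIL all reach their frail scores, while
non-frail participants have deficits removed until all three sit below.
Raw fields are then realized away from every cutoff (e.g. grip uniformly
0.5–12 kg below or 0.5–14 kg above the sex cutoff), so the scorers
reproduce the latent status for 100% of participants — by construction,
and verified by test. One latent status drives all three indices; the
configured prevalence is therefore a single number, matching the three
observed index prevalences (18–21%) only jointly, not separately.

**Seeding.** One master seed; each participant owns three derived streams
(demographics/targets, synthesis, criterion fields) produced by a
counter-based integer hash, so growing a cohort extends it without
reshuffling earlier participants.

## Default study conditions

Defaults emulate a geriatric-outpatient study setting: n = 277, 63.2% women, latent
prevalence 0.19, and effect ORs A1 0.84 (per 1), A2 1.26 (per 0.1),
A3 1.04 (per 10 Hz), A4 1.35 (per 0.1). The acoustic operating point is
`elderly_vowel_spec()` — f0 140 Hz, jitter 0.005, shimmer 0.06, drift
3 Hz, noise 0.05 — an older speaker's moderately perturbed /a/; feature
means and SDs (A1 0.115 ± 0.012, A2 0.085 ± 0.010, A3 18 ± 6 Hz,
A4 0.04 ± 0.012) were fixed once from the chain's achievable ranges at
that spec. These are the package's chosen
conditions, not estimates of any clinical study's unpublished feature
distributions: raw sustained-vowel corpora of this kind are rarely
deposited and legacy analysis settings (proprietary toolchains, unstated
frame-length units) are not recoverable, so numeric equality with
published clinical ORs is out of reach by design; what the synthetic
cohort supports is *methodological* validation — oracle identities, monotonicity, type-I error, and recovery
of known effects.

What the generator does **not** emulate: phonetic realism or perceptual
quality; sex- or age-dependent f0 and formants (baseline features are
sex-neutral, so stratified null behavior is clean); session effects,
room acoustics, microphone coloring; within-person repeat variability;
correlations between criterion fields beyond those induced by the latent
status; and any voice–frailty pathway other than the configured logistic
link. Passing tests therefore demonstrate that the measurement and
inference chain is correct, not that real frail voices behave this way.

## Numerical notes

* LPC polynomial roots are found by Durand–Kerner iteration warm-started
  from the previous frame's roots (consecutive frames share poles),
  falling back to the companion-matrix eigenvalue routine on
  non-convergence; a degenerate autocorrelation marks the frame invalid
  rather than erroring.
* Isotonic calibration curves get a strictly-increasing jitter of 1e-9
  before inversion so flat segments remain invertible.
* The ANOVA guard returns F = 1e12, p = 0 when within-group variance is
  exactly zero with differing means.
* Wald CIs use 1.96·SE on the log-odds scale; profile-likelihood CIs were
  considered and left out (the reported CIs are Wald-shaped, and the
  package's CIs are used only against its own simulations).
* Problem sizes in the test suite: parameter recovery uses 20 cohorts of
  n = 500; null calibration 200 cohorts of n = 200; the sex-interaction
  contrast 20 cohorts of n = 250 with an 8× female A4 multiplier (chosen
  by a power calculation so the mechanism check is not dominated by
  stratified-fit noise).

## Known limitations

* A1's noise sensitivity couples it strongly to A4 (r ≈ 0.7 in synthetic
  cohorts); with the default (noise-positive) effect structure, A1's
  univariate OR absorbs part of the A4 effect, as it would in any real
  univariate analysis of correlated features.
* A2's achievable range at the default operating point is narrow
  (≈ 0.05–0.10), so configured A2 SDs much above 0.015 truncate.
* The FRAIL index's fatigue item reuses the CHS exhaustion question and
  SOF's energy item is a separate question; the generator realizes them
  as distinct deficits, which slightly understates their real-world
  correlation.
* Firth fallback SEs use the unpenalized information at the penalized
  estimate — adequate for flagging, not for publication-grade inference
  under separation.
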