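---
title: "Mapping perceptual vowel spaces from the Acoustic Change Complex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping perceptual vowel spaces from the Acoustic Change Complex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accmap)
```

## The method

When an ongoing sound changes — here, one sustained vowel giving way to
another — auditory cortex produces a characteristic evoked response, the
Acoustic Change Complex (ACC), peaking roughly 200 ms after the change with
a frontal-central scalp distribution. Because a concatenated vowel sequence
elicits one ACC per transition, several transitions per second, a single
passive EEG session can measure neural discriminability for *every* pair of
a vowel inventory at once. With 7 vowels there are 42 ordered transitions,
i.e. 21 vowel pairs in two presentation orders.

`accmap` implements the full chain:

1. **Stimuli.** One sustained token per vowel, pitch-flattened to the
   talker's average F0 and envelope-flattened so loudness cues cannot drive
   the response; tokens are spliced into random sequences (segments of
   300–400 ms, 50 ms raised-cosine cross-fades), each splice logged as a
   transition event.
2. **Acoustic predictors.** Per unordered pair, the cochlear-scaled
   spectral difference (mean absolute level difference between auditory
   excitation spectra) and the absolute F1 and F2 differences.
3. **Synthetic EEG.** A generator that plants ACC responses at the event
   times under a configurable age-specific sensitivity model — the testbed
   standing in for infant recordings, which are not distributable.
4. **Preprocessing.** Mastoid-average reference, 0.1–30 Hz zero-phase
   Butterworth filtering, posterior-channel exclusion, neighbour
   interpolation, epoching at −100..+350 ms with baseline subtraction, and
   ±150 µV artifact rejection.
5. **DSS.** Denoising Source Separation extracts, per subject, the single
   linear channel combination maximizing trial-to-trial repeatability, and
   projects it back to the maximum-amplitude electrode so magnitudes stay
   in microvolts.
6. **Statistics.** Windowed ACC magnitudes per ordered pair; one-way
   ANOVAs per pair across age groups; mixed-effects models of magnitude on
   the acoustic predictors with age interactions; order-asymmetry tables.
7. **Maps.** Classical MDS (with the Cailliez additive constant) of the
   group-mean magnitudes into two dimensions, plus Procrustes alignment
   for cross-group comparability.

## The DSS criterion

Let $C_0$ be the covariance of the concatenated single-trial data and $C_1$
the covariance of the trial average. Whitening by $C_0$ (PCA retaining
99.9% of variance, a guard against rank deficiency after interpolation and
re-referencing) and eigendecomposing the whitened $C_1$ yields components
ordered by the ratio of evoked to total variance — the repeatability score
$\lambda_1 \in [0, 1]$. Identical trials give $\lambda_1 = 1$; pure noise
gives $\lambda_1 \approx p/n$. The first component is retained per subject,
fitted on all conditions pooled. The rank-1 reconstruction uses the
covariance pattern $a = C_0 w / (w^\top C_0 w)$, which returns a noiselessly
planted source at its true amplitude; the reporting electrode is the
channel where the reconstructed trial average is largest, and the pattern
is kept positive there so the component carries the sensor polarity.

## Windowed mean versus windowed max

Two magnitude definitions are computed for every ordered pair: the mean
and the maximum of the condition-average response over 0–350 ms (columns
`acc_mean_uv` and `acc_max_uv`). They are not interchangeable in this
paradigm. With segments of 300–400 ms and a response kernel supported on
0–350 ms, the *previous* transition's P2 peak falls inside the *current*
epoch's baseline window, and the next transition's onset response enters
the analysis window. The windowed mean is therefore contaminated by a term
that depends on the expected response to the preceding transition — a
systematic, condition-correlated bias inherent to the stimulus timing (it
would affect recordings of real subjects equally). The windowed max,
taken at the P2 latency where the neighbouring responses are near zero,
is far more robust: in noiseless simulations it tracks planted amplitudes
at r ≈ 0.98 versus ≈ 0.77 for the windowed mean. The end-to-end analyses
and the perceptual maps consequently default to the windowed max, while
the windowed mean remains available for model-based analyses where a
common offset is absorbed by the intercept. Recovered magnitudes carry a
roughly constant negative offset (baseline contamination plus band-pass
attenuation); correlations, coefficient signs and maps are unaffected, and
negative group means for near-indiscriminable pairs are clamped to zero
when forming dissimilarity matrices.

## What the generator emulates — and what it does not

The synthetic-EEG generator plants `amplitude(from, to) × topography ×
kernel` at each event over pink (1/f) noise of 8 µV RMS per channel, 1 µV
sensor white noise, and raised-cosine frontal blink artifacts of 200 µV at
2/min — large enough to exercise the rejection rules. The tri-phasic
kernel (P1–N1–P2-like, unit peak at 200 ms, support 0–350 ms) and the
bilateral frontal-central topography are smooth idealizations; subjects
differ only by a log-normal gain (σ = 0.2), which motivates by-subject
random intercepts downstream.

Two age presets define the planted sensitivity. The *young* preset is
linear in the formant differences, `a·|ΔF1| + b·|ΔF2| + c` with defaults
a = 0.010 µV/Hz, b = 0.002 µV/Hz, c = 1 µV, so responses track raw
acoustics with F1 dominant. The *old* preset saturates in |ΔF1|
(`c + A(1 − exp(−|ΔF1|/knee))`, A = 5 µV, knee = 120 Hz) and adds a 2 µV
boost for the three pairs with the smallest cochlear-scaled difference —
selective gain for confusable pairs, the perceptual-warping signature. An
order asymmetry of ±0.75 µV makes transitions *into* /ɔ/ stronger than
transitions out of it (signed difference 1.5 µV). These values were chosen
once to give single-trial SNR and group-level effect sizes of realistic
order for infant EEG; they are parameters, not calibrated constants.

What the generator does **not** model: real infant movement artifacts and
non-stationary noise, volume-conduction from a realistic head, latency
jitter or topography differences across subjects and ages, and habituation
over the session. Passing the recovery tests therefore demonstrates that
the pipeline is correct and unbiased under known ground truth — not that
infant data of this difficulty would yield equally clean estimates.

## Numerical and design choices

* **Vowel synthesis** uses an impulse train with a mild one-pole spectral
  tilt through a cascade of resonators (bandwidths 60/90/120 Hz). A
  periodic source has no energy between harmonics, so the spectral peak of
  a token can match F1 to 5% only when F1 spans several harmonics; the
  tests verify the property at low f0 and, at the talker's 185 Hz, for the
  open vowels.
* **Pitch flattening** is pitch-synchronous overlap-add with
  autocorrelation epoch marking; tolerance ±2 Hz frame-wise. The envelope
  is flattened by full rectification plus a 50 Hz zero-phase low-pass,
  with samples below 1% of the median envelope clamped before division.
* **Filters**: separate 4th-order Butterworth high-pass (0.1 Hz) and
  low-pass (30 Hz) sections, each forward-backward — zero phase, so the
  ACC latency is untouched; a single band-pass design at a normalized
  cutoff of 8·10⁻⁴ would be numerically fragile.
* **Rejection** is two-stage: a ±500 µV gross sensor-space pass protects
  the DSS covariance estimates, then the ±150 µV rule is applied to the
  back-projected component traces (sensor-space application is available
  via `reject_on = "sensor"`).
* **Interpolation** is inverse-distance weighting over the 4 nearest
  non-excluded channels on the schematic 2-D layout.
* **The ERB filterbank** uses Glasberg–Moore ERB-number spacing at
  0.5-ERB steps from 50 Hz to 11 kHz with symmetric roex(p) weighting and
  a −60 dB level floor relative to the maximum band. Band levels are
  absolute dB so the spectrum is dB-linear in waveform gain; spacing and
  the floor are configurable.
* **MDS** is `stats::cmdscale(add = TRUE)` (Cailliez constant). Negative
  residual eigenvalues are excluded from coordinates but reported. Two fit
  indices are kept: `vaf`, the squared Pearson correlation between fitted
  distances and input dissimilarities (×100), and `gof`, the
  eigenvalue-ratio fit; the reported percentage is `vaf`.
* **Procrustes alignment** is the closed-form SVD similarity transform
  (translation, rotation, reflection, uniform scale).
* **Subject inclusion** applies the 1800-event cutoff to the number of
  recorded transitions, before artifact rejection.

## Problem sizes

Simulated cohorts default to the 16-channel montage at 256 Hz — ample for
a response band-limited at 30 Hz — with 15 virtual subjects per age preset
and ~100 trials per ordered transition in the full-scale checks (4201
segments, ~21 minutes of recording per subject, comparable to a real
session). The acceptance script uses 10 subjects × 50 trials per ordered
pair per cohort; unit tests use smaller cohorts. The paper-faithful
2048 Hz / 32-channel configuration is available through the `fs` and
`mont` arguments.

## Known limitations

* The exact recipe behind the cochlear-scaled spectral difference in the
  original literature is not fully specified; this implementation
  documents its own (roex excitation spectra, mean absolute dB
  difference) and exposes the knobs. Only qualitative behaviour (metric
  properties, ordering of near versus far pairs) is guaranteed.
* Whether epochs should be time-locked to cross-fade onset, midpoint or
  offset is unspecified in the source paradigm; events mark the cross-fade
  onset. The 25 ms ambiguity shifts latencies, not magnitudes.
* The windowed-mean magnitude is biased by response overlap at this
  stimulus rate (see above); analyses default to the windowed max.
* Recordings are kept in an in-memory container with TSV/JSON export; no
  EDF writer is bundled.
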