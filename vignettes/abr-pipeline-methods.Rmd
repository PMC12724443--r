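---
title: "Methods: ABR signal processing, response strength and thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ABR signal processing, response strength and thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

The auditory brainstem response (ABR) is a microvolt-scale potential
evoked by brief sounds, recorded from scalp electrodes and resolved by
averaging over many stimulus repetitions. `abrkit` implements the
offline computational path of a click-ABR measurement system for mice:
decoding raw acquisition frames, filtering, trial averaging with
artifact rejection, a peak-agnostic response-strength statistic, and
interpolated hearing thresholds from which hearing-loss threshold
shifts are derived. This vignette records the models, the parameter
choices, and the reasoning behind the places where the design was
genuinely open.

## Recording model

The montage is three differential channels -- `LV` (left ear minus
vertex), `RV` (right ear minus vertex) and `LR` (left minus right) --
plus a `speaker` channel that records the voltage across the
loudspeaker for stimulus alignment. By construction `LR = LV - RV`:
any one of the three electrode channels is a linear combination of the
other two, and the pipeline preserves this identity through filtering
and averaging (it is a standing test invariant).

The acquisition front end is a 24-bit delta-sigma converter sampling at
16 kHz. At gain 24 with a 4.5 V reference, full scale is
±187 mV and one code step is 22 nV (`2 * (4.5 / 24) / 2^24`), a dynamic
range of almost seven orders of magnitude. The reference voltage is not
part of the published hardware description; 4.5 V is the chip's internal
reference, and it is the value that makes the printed ±187 mV / 22 nV
pair exact, so `device_profile()` adopts it and documents the
inference. Each input also sees a passive RC pole from the electrode
impedance (nominally 10 kΩ) and a 4.7 nF capacitor to ground, a ~3.4 kHz
lowpass modeled by `prefilter_cutoff()` / `prefilter_gain()`.

Stimuli are single-sample clicks of alternating polarity, delivered at
an irregular ~8 Hz and at one of 13 levels from 25 to 73 dB SPL in 4 dB
steps. A click's level is defined by dividing its maximum peak-to-peak
sound pressure by 100 -- the ratio of the ~50 ms loudness-integration
window of the auditory system to the ~0.5 ms effective click duration --
and referring the result to 20 µPa. An rms-over-50 ms variant
(`mode = "rms"`) is provided and gives similar values. Time zero is
speaker onset; the ~0.4 ms acoustic propagation delay to the ear is
deliberately not subtracted, matching how latencies are reported.

## Pipeline

1. **Band filtering** (`bandpass_filter`): 2nd-order Butterworth,
   300--3000 Hz ("ABR band"), applied forward and backward
   (`signal::filtfilt`). Zero-phase filtering is essential here: the
   primary peak latency (~1.4 ms) and the ~7 µs/dB latency shift would
   otherwise be confounded by the filter's group delay. The
   forward-backward pass doubles the effective attenuation; we state
   the design order, not the realized one. A 20--500 Hz band serves ECG
   inspection and a 0.1 Hz highpass serves raw-trace display.
2. **ECG detection** (`detect_ecg`): heartbeats appear as ~30 µV spikes
   at 3--4 Hz on all channels and are detected on the 20--500 Hz band by
   thresholding at six robust standard deviations with a 150 ms
   refractory interval. Six (rather than the five used for the much
   sparser click events) keeps the expected number of chance crossings
   in a multi-minute recording below one; beats exceed the in-band
   background about twenty-fold, so sensitivity is not at issue. Events
   within one period of the band's low edge of either end of the
   recording are ignored -- zero-phase IIR filtering leaves edge
   transients there. The heart rate, `(beats - 1) / span`, is a useful
   anesthetic-depth indicator; values outside 2--8 Hz warn rather than
   error.
3. **Epoching** (`epoch_trials`): trials span 2.5 ms before to 7.5 ms
   after each click (160 samples at 16 kHz; half-open sample window),
   labelled with level and polarity. Partial windows at the recording
   edges are dropped, not padded.
4. **Outlier rejection** (`reject_outliers`): per channel, each trial is
   summarized by its maximum absolute value and its rms over the full
   epoch; a trial is dropped when either statistic exceeds the mean
   across all trials by at least three standard deviations. This is a
   single pass over the whole recording, before grouping by level:
   artifacts (mostly ECG overlaps) are properties of the trial, not of a
   level. The "typical trial" is the mean of the statistic; a median
   mode is available (`rejection_center = "median"`). A trial rejected
   on any channel is rejected on all channels, since the three channels
   share one animal and one artifact.
5. **Averaging** (`average_by_level`): arithmetic mean of the included
   trials of each (channel, level) cell. When both click polarities are
   present the pooled mean is the unweighted mean of the two
   per-polarity means: any electrical stimulus artifact flips sign with
   click polarity, so balanced pooling cancels it *exactly* even when
   polarity counts are unequal (with plain pooling, a 1 µV artifact and
   a typical ±√n count imbalance would leave a residual comparable to
   the noise floor). The baseline rms of the average over −2.5 to
   −1.25 ms tracks the noise floor and declines as n^(−1/2); with the
   typical 100--300 trials per level it lands at 0.05--0.15 µV.

## Response strength and thresholds

The response strength at a timepoint is the sample standard deviation
(denominator n−1) of the averaged waveform over a 1.25 ms window
centered there (20 samples; the window at index i covers samples
i−10..i+9, so the read-out at t = −1.875 ms spans exactly the −2.5 to
−1.25 ms baseline). The scalar strength is read at t = +2.0 ms, where
the rolling SD tends to peak. This statistic deliberately avoids
identifying individual peaks, which are variable across animals.

The hearing threshold is the level at which the scalar strength crosses
0.3 µV, linearly interpolated between tested levels; 0.3 µV exceeds the
baseline strength of noise-only averages over 99% of the time, so false
positives are rare. Interpolation is linear in (level, strength) as
stated, although strengths are usually plotted on a log axis; a
log-strength interpolation is available (interpolate the criterion in
log space before inverting). If the strength curve is non-monotone the
*highest-level* crossing is used, which is robust to spurious low-level
bumps. Estimates are censored `below_grid` / `above_grid` when the
criterion is met everywhere or nowhere, and censored post-intervention
estimates propagate into `threshold_shift()` as lower bounds.

The primary peak -- the large early negative deflection, negative
because the ear electrode is the non-inverting input -- is located as
the most negative sample in 0.5--2.5 ms, refined by parabolic
interpolation over three samples. Latency shifts across levels are
measured by normalized cross-correlation against the loudest level with
parabolic sub-sample refinement: the 62.5 µs sampling period is an
order of magnitude coarser than the ~6.9 µs/dB effect being measured.
The lag search window defaults to ±0.5 ms, *half the ~1 ms oscillation
period* of the response: the cross-correlation of a quasi-periodic
wavelet has secondary maxima one carrier period away, and a wider
window lets noise-dominated levels lock onto those cycle-skipped peaks.
Levels whose peak correlation falls below 0.3 are excluded from the
latency fit as having no detectable response.

Sample standard deviations use denominator n−1 throughout (rolling
strength, rejection statistics); the convention matters at the 20-sample
window scale and is stated here because the source description is
silent on it.

## Synthetic sessions

`generate_session()` produces raw recordings with the statistical
structure the pipeline assumes, so every stage is testable without
hardware:

* three latent sources (left ear, right ear, vertex) differenced into
  LV/RV/LR, so the channel algebra holds exactly; optional independent
  per-channel instrumentation noise breaks it on request;
* 1/f background noise (spectrally shaped Gaussian noise), calibrated
  per realization so each electrode channel carries exactly the
  configured 300--3000 Hz rms (default 1.5 µV, the top of the observed
  1--1.5 µV range);
* ECG: a Ricker-wavelet template at 3.5 Hz with 10% interval jitter,
  scaled so its ABR-band peak is 30 µV; breathing: a ~100 µV, 1 Hz
  artifact (removed entirely by the ABR band);
* clicks: truncated-exponential intervals on [80, 200] ms with mean
  ~125 ms (~8 Hz, irregular), uniform random levels and polarities;
* the evoked response: a Gabor-like damped cosine (1 kHz carrier,
  0.5 ms Gaussian envelope) whose most negative extremum sits at 1.4 ms
  at the loudest level and is delayed 6.9 µs/dB below it, with an
  additional 0.03 ms on the right-ear source (interaural distance);
* response magnitude: a softplus of level above `true_threshold_db`
  (width 4 dB), calibrated so the *scalar strength* of the noiseless
  wavelet at the loudest level is 3.45 µV -- the size of a typical
  primary peak. This makes the strength-level curve cross the 0.3 µV
  criterion within about 2 dB of `true_threshold_db`, which is what
  parameter-recovery tests exploit; it is a test calibration, not a
  claim about cochlear physiology.
* an optional electrical stimulus artifact whose sign follows click
  polarity, for exercising balanced-polarity cancellation; and an
  optional mains-interference term.

Each component draws from its own RNG substream derived from the master
seed, so disabling one component leaves the others byte-identical.
Output is quantized to the float32 storage precision at generation, so
a disk round trip is bit-exact.

What the generator does *not* emulate -- and hence what passing tests do
not show about real data: real left- and right-ear generators differ in
waveform shape, not just gain and delay, so real LR channels carry
responses comparable to LV/RV while synthetic LR responses are the
small difference of two similar wavelets (synthetic LR thresholds are
accordingly elevated and are not used for parameter-recovery checks).
Real ECG morphology, level-dependent waveform shape changes,
non-stationary noise, electrode drift and speaker nonlinearity (±2 dB)
are likewise out of scope. Nominal rather than per-level-calibrated
sound levels are used throughout.

## Problem sizes and numerical choices

Simulation-based checks use the scales of a real experiment: recovery
runs use ~125 trials per level (200 s sessions; real recordings contain
100--300 per level), the latency-slope run uses ~295 per level (480 s),
and noise-floor statistics use 100-trial averages. The averaging noise
law is verified on curves pooled over several sessions and channels:
a single recording's subsample curve flattens at large n around its one
realized grand mean (whose rms is itself a ~σ/√N random quantity), so
the −1/2 slope is a property of the ensemble, not of each recording.

Degenerate inputs are handled explicitly: constant waveforms have
undefined click levels (error) and zero rolling strength; a digitally
silent speaker channel falls back from the MAD-based click threshold to
a fixed fraction (1/500) of the largest event; epochs that do not fit
the recording are dropped and counted; a strength exactly at the
criterion is a valid crossing landing on the tested level; rejection
with zero variance across trials rejects nothing.

## Limitations

Thresholds depend on the 0.3 µV criterion, the trial count and the
noise level; like any ABR threshold they are most interpretable as
within-study differences (e.g. pre/post shifts) rather than absolute
values. The latency fit assumes a rigid waveform shift across levels;
real waveforms also change shape. The ANOVA-style group statistics on
peak magnitudes are out of scope -- the package computes the peak
magnitudes that such analyses consume.
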