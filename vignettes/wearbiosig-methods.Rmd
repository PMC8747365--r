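---
title: "Methods: simulating and analyzing wearable ECG/EMG telemetry"
author: "wearbiosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing wearable ECG/EMG telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wearbiosig)
```

## What the package models

`wearbiosig` is a software model of a single-channel wearable biopotential
monitor and its host-side processing chain. The signal path it reproduces
is:

1. **Body** — synthetic ECG (PQRST morphology driven by a beat schedule)
   or surface EMG (band-limited stochastic carrier shaped by an activation
   envelope), plus additive contamination: mains interference with
   harmonics, slow baseline wander, broadband noise.
2. **Device** — a digitally simulated analog front-end (AFE): 2nd-order
   high-pass, amplified 2nd-order low-pass (total gain 1100 V/V), an
   optional notch at the mains frequency standing in for the analog twin-T
   network, mid-rise ADC quantization (8-bit default over a 3.3 V span)
   at 10 kSps, and packetization into 24 ms telemetry bursts of 240
   samples.
3. **Host** — reassembly of the burst stream, periodic FFT-based
   assessment of powerline interference (PLI), an IIR notch cascade whose
   order (0–12, even) adapts to the measured PLI level, and downstream
   analytics: gradient-threshold R-peak detection, R-R intervals, windowed
   BPM, time/frequency-domain HRV, rectified/RMS EMG intensity, and
   Bland–Altman plus Wilcoxon signed-rank method agreement.

Every generator returns the exact ground truth it used (beat schedule,
activation profile), so each downstream stage can be validated against
known labels without any external recordings.

## Synthetic signal generators

**ECG.** Each beat is a sum of five Gaussians (P, Q, R, S, T) with
amplitudes in mV, and offsets/widths in seconds defined for a 1-second
reference beat (defaults: P 0.15 mV at −200 ms, Q −0.10 at −30 ms,
R 1.00 at 0, S −0.15 at +30 ms, T 0.30 at +250 ms). The template time
axis scales linearly with the local R-R interval (clamped to [0.2, 1.2]),
imitating rate-dependent compression of the cardiac cycle; without this,
schedules above roughly 90 bpm would overlap adjacent templates. Setting
`scale_with_rr = FALSE` freezes the template, in which case schedules
whose intervals are shorter than the template support are rejected.
Beat-to-beat variability is imposed on the schedule itself, either as a
sinusoidal interval modulation (frequency in Hz, depth in ms — a stand-in
for respiratory and autonomic rhythms) or as i.i.d. Gaussian jitter.

**EMG.** White Gaussian noise is shaped by a zero-phase 20–450 Hz
band-pass, normalized to unit RMS, then multiplied by
`carrier_sd * envelope(t)` where the envelope is piecewise-constant in
[0, 1]. The windowed RMS of the output therefore tracks
`carrier_sd * envelope` directly. The default band sits comfortably
inside the EMG channel's 40.17–727 Hz front-end bandwidth.

**Interference.** Deterministic sinusoids at the mains frequency and its
harmonics (phases fixed at zero so injections are exactly reproducible),
a sub-0.5 Hz sinusoidal baseline wander, and seeded white noise. Variances
add: over a minute or more the variance of (noisy − clean) equals the sum
of injected component variances to within 2%.

**What the generators do not emulate:** electrode–skin impedance,
motion-artifact biomechanics, multi-lead geometry, ectopic beats, and
non-stationary mains amplitude. Passing tests therefore demonstrate
correctness of the processing chain on idealized physiology, not clinical
performance on real recordings.

All randomness flows through explicit `seed` arguments (the caller's RNG
state is saved and restored), so identical seeds give bit-identical
signals.

## The analog front-end, digitally

The analog stages are simulated as digital biquads at the device sampling
rate. The band-limiting stages are 2nd-order Butterworth sections obtained
by bilinear transform with frequency prewarping, so the realized −3 dB
point lands exactly on the requested cutoff (ECG 0.34–41 Hz, EMG
40.17–727 Hz); `find_minus3db()` recovers these edges by bisection on the
magnitude response and the tests require agreement within 1% of the
cutoff. The filter family is a design choice: "second-order filter with a
cutoff" is read as the conventional monotone (Butterworth) response.

The analog twin-T notch is represented by its standard digital equivalent:
a constrained 2nd-order notch biquad with unity gain at DC and Nyquist and
a transfer-function zero at the center frequency, parameterized by (f0, q)
with q = 5 by default — wide enough to be robust, while costing the 41 Hz
ECG band edge less than 1 dB. Total gain is applied as one multiplier at
the low-pass stage; gain distribution across stages is not externally
observable, and the small dual-channel loading loss is modelled as an
optional scalar derating (default 1).

The ADC is a uniform mid-rise quantizer over a configurable full scale,
by default ±1650 mV — a 3.3 V span centered on the mid-scale reference
level the device establishes before conversion. Out-of-range samples clip
to the edge codes and are counted rather than raised as errors; in-range
reconstruction error is at most half an LSB. Packetization slices the code
stream into `fs × 24 ms` frames (240 at 10 kSps); a trailing partial frame
is zero-padded and flagged with its pad count, and
`depacketize(packetize(x))` is exact for any length.

## Adaptive host-side filtering

Once enough signal has arrived, and then at every assessment period
(default 60 s), the host computes a periodogram of the trailing analysis
window, integrates the power within ±1 Hz of the mains frequency, and
forms the PLI ratio (band power over total non-DC power). Six strictly
increasing thresholds, log-spaced from 0.01 to 0.5 by default, map the
ratio to an even notch order: below the first threshold the filter is
bypassed (order 0); a dominant line selects the full order 12. Only
the endpoints and monotonicity are contractual; the mid-table placement is
configurable.

Two numerical decisions deserve note:

* **Analysis window.** The device's own logging granularity (24 ms) gives
  only ~42 Hz spectral resolution at 10 kSps — too coarse to separate a
  50/60 Hz line from the signal band. The default analysis window is
  therefore 1 s; the literal 24 ms window remains available via
  `adaptive_policy(analysis_window = 0.024)` for fidelity experiments.
* **Cascade shape.** The order-N filter is N/2 identical 2nd-order notch
  sections at the mains frequency. With a fixed per-section Q, deepening
  the cascade also widens its bite and adds group delay at QRS
  frequencies; an order-12 cascade of Q = 5 sections delays detected
  R-peaks by ~7 ms relative to an unfiltered path. Per-section Q therefore
  scales as `q × order/2` (order 12 → Q 30 sections), which keeps the
  passband probe at 10 Hz within 0.03 dB of unity, deepens in-band
  rejection strictly with order, and holds the systematic R-peak delay
  under 5 ms.

Filtering is strictly causal and streaming: biquad state is carried across
bursts exactly, so burst-wise output is bit-identical to filtering the
concatenated record with the same coefficients. On an order change the
new filter's state is primed by replaying the trailing 0.5 s of input
(`reprime = "reset"` zeroes it instead), which suppresses coefficient-swap
steps. A consequence of causality is a startup window: the filter cannot
engage before the first assessment, so comparative analyses (clean versus
contaminated runs) should exclude the first few seconds — `run_session()`
exposes `analysis$trim_start` for exactly this.

## R-peak detection

The detector follows the gradient-threshold scheme: first difference →
25 ms moving-average smoothing → adaptive threshold → 200 ms refractory
suppression → localization at the signal maximum near each crossing.
The threshold is 0.4 × a rolling statistic of the smoothed absolute
gradient over the trailing 5 s. The statistic is the rolling **maximum**
(quantile level 1.0, exposed as `stat_quantile`): with realistic PQRST
morphology the QRS occupies only ~2–3% of samples, so a 95th-percentile
statistic sits in the P/T-wave gradient range and 0.4× of it false-triggers
on T waves; 0.4× the maximum cleanly separates QRS upslopes from P/T
activity across 40–180 bpm. A final amplitude gate (peak height above the
local median ≥ 3.5× the local RMS) rejects candidates that do not stand
out of the background; flat input yields an empty series rather than an
error. All constants are parameters; the tests assert detection
properties (per-beat sensitivity and positive predictive value, ≤ 5 ms
localization), not the constants.

Interval-level artifact rejection is available downstream: intervals
outside 0.3–2.0 s are excluded by the schedule/refractory invariants by
construction in synthetic work, and the alignment step of the agreement
module counts (rather than silently drops) unmatched intervals.

## HRV conventions

* SDNN uses the sample standard deviation (n−1). RMSSD is the root mean
  square of successive differences. Both are checked against direct-formula
  oracles to 1e−9 and against the closed forms for i.i.d. intervals
  (sdnn → σ, rmssd → σ√2).
* Frequency-domain analysis resamples the interval tachogram at 4 Hz by
  cubic spline, removes a linear trend, and estimates the PSD by Welch's
  method (Hann window, 50% overlap). LF is 0.04–0.15 Hz and HF
  0.15–0.4 Hz — the standard short-term bands. Normalized units are
  percentages of (LF + HF), so `lf_nu + hf_nu = 100` holds exactly and
  `lf_hf = lf_nu / hf_nu` whenever HF > 0; a worked consistency example:
  LF 77.7 nu and HF 22.3 nu imply LF/HF = `r round(77.7 / 22.3, 2)`.
* Windowed BPM is `60000 / mean(intervals)` per window (default 30 min);
  windows with fewer than two intervals are flagged missing rather than
  interpolated.

## EMG intensity

Rectification is the absolute value; integrated EMG (iEMG) is the
rectified sum × sample period per window — the classical definition;
windowed RMS (default 200 ms, non-overlapping) is the primary intensity
measure. The linear envelope is rectification followed by a zero-phase
2nd-order low-pass at 5 Hz (both cutoff and causal/zero-phase mode are
parameters). The long-horizon summary averages window RMS over 30-min
blocks and normalizes by the session maximum — chosen as the denominator
because it guarantees values in [0, 1] with the most active block at
exactly 1; an all-zero session is defined to yield zeros. Both RMS and
iEMG are computed throughout, since "intensity" is used for either in
practice; plots and reports default to RMS.

## Method agreement

Differences are fixed as (device − reference). Bland–Altman reports the
mean difference (bias), the n−1 standard deviation of differences, and
limits of agreement bias ± 1.96 SD; both bias ± SD and the explicit LoA
are reported because the two summaries are easily conflated. The Wilcoxon
signed-rank test drops zero differences, midranks ties, and computes the
exact two-sided p by full enumeration of the sign-assignment null
(evaluated with a generating-function recursion, so exactness costs
polynomial not exponential time) up to n = 24, switching to the normal
approximation with continuity and tie corrections beyond. R-R series from
two instruments are paired by interval mid-times within a 250 ms default
tolerance; EMG series pair naturally on common 200 ms windows.

## Problem sizes and numerical tolerances

The test suite validates the full pipeline at desk scale: sessions of
30 minutes at 1 kHz (ECG) and 2 kHz (EMG) — rates chosen to keep
`fs × 24 ms` integral as packetization requires — with 300 s analysis
windows for ramp/bout recovery; detector sweeps run 40–180 bpm at 1 kHz
for 40–60 s per rate. Oracle agreements (hrv_time, windowed RMS,
Bland–Altman) are asserted to 1e−9 relative or better; filter cutoffs to
1% of the cutoff; exact Wilcoxon p to 1e−12 against literal 2^n
enumeration. Filtering at the device's native 10 kSps is exercised in the
filter-design and packetization tests; long sessions use the lower rates
purely as a choice of simulation scale.

## Known limitations

* The detector is tuned for adult resting-to-exercise rates (refractory
  200 ms caps detectable rate at 300 bpm) and assumes upright R waves.
* The adaptive filter tracks a single mains fundamental; harmonics are
  attenuated only by the front-end low-pass, not notched.
* Quantizer saturation is counted, not compensated: interference that
  drives the amplified signal beyond full scale produces clipping
  harmonics no later notch can remove.
* The BLE link is modelled as lossless, in-order 24 ms bursts; the gap
  policy (error or flagged zero-fill) stands in for real loss handling.
* Reported HRV metrics follow one convention set (n−1 SDNN, 4 Hz spline
  resampling, Welch PSD); other toolchains' conventions differ by a few
  percent on short records.
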