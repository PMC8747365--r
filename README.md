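# wearbiosig

Simulation and analysis of the signal path of a wearable single-channel
ECG/EMG monitor: from synthetic biopotentials with known ground truth,
through a digital model of the device's analog front-end and 24 ms burst
telemetry, to host-side adaptive powerline-interference removal and the
standard downstream analytics — R-peaks and heart-rate variability for
ECG, rectified/RMS intensity for EMG, and method-agreement statistics.

It is written for signal-processing and digital-health engineers who need
a fully testable, deterministic stand-in for a hardware telemetry chain:
every stage can be validated against the exact beat schedule or activation
envelope that generated its input.

## The model in brief

**Front end.** Each channel is band-limited by 2nd-order Butterworth
stages (ECG 0.34–41 Hz, EMG 40.17–727 Hz), amplified ×1100, optionally
notched at the mains frequency (the digital equivalent of an analog twin-T
network), quantized by a mid-rise 8-bit ADC at 10 kSps, and transmitted as
bursts of 240 samples every 24 ms.

**Adaptive filtering.** The host periodically takes an FFT of the trailing
signal window and forms the powerline-interference ratio

```
pli_ratio = P(f_mains ± 1 Hz) / P(total, excl. DC)
```

which selects the order N ∈ {0, 2, …, 12} of an IIR notch cascade (N/2
biquad sections at the mains frequency): no interference → the filter is
bypassed; a dominant line → the full 12th-order cascade. Filtering is
causal and streaming, with exact state carry-over across bursts.

**Analytics.** R-peaks are detected on the smoothed waveform gradient with
an adaptive threshold and refractory suppression; R-R intervals yield
windowed BPM, SDNN and RMSSD (time domain) and LF/HF normalized units
(0.04–0.15 / 0.15–0.4 Hz, Welch PSD of the 4 Hz-resampled tachogram, with
lf_nu + hf_nu = 100). EMG is rectified and summarized as 200 ms windowed
RMS, integrated EMG, a 5 Hz linear envelope, and session-normalized 30-min
intensity. Paired series from two instruments are compared by Bland–Altman
bias ± 1.96 SD limits of agreement and the exact Wilcoxon signed-rank
test.

## Worked example

A 330 s ECG at 72 bpm with 0.1 Hz sinusoidal rate modulation is
contaminated with a strong 60 Hz line (2 mV), pushed through the front-end
and burst telemetry, adaptively filtered, and analyzed:

```r
library(wearbiosig)

sch <- beat_schedule(duration = 330, mean_hr = 72,
                     hrv = list(type = "sinusoidal", freq = 0.1, depth_ms = 40))
ecg <- generate_ecg(sch, fs = 1000)
noisy <- add_interference(ecg$signal,
                          interference_spec(mains_freq = 60,
                                            harmonic_amplitudes = 2),
                          seed = 7)

cfg <- afe_config("ECG", fs = 1000, notch_enabled = FALSE, total_gain = 200)
bursts <- packetize(quantize(apply_afe(noisy, cfg), cfg), 1000, mode = "ECG")
out <- stream_filter(bursts, adaptive_policy(assessment_period = 30), cfg)
out$reports[[1]]
#> <noise_report> pli_ratio 0.9424 -> IIR order 12

peaks <- detect_r_peaks(out$signal)
peaks
#> <rpeak_series> 390 peaks
rr <- rr_intervals(peaks)
hrv_time(rr)
#> $sdnn
#> [1] 28.33747
#> $rmssd
#> [1] 14.7807
hrv_freq(rr)
#> <hrv_report> LF 99.9 nu, HF 0.1 nu, LF/HF 900.42

agreement_report(align_rr(rr, rr_intervals(sch$beat_times)))
#> <agreement_report> bias -0.000 +/- 0.128 (sd), LoA [-0.252, 0.252], n=389
#>   Wilcoxon signed-rank: V = 38188, p = 0.9067
```

Reading the output: the first noise assessment sees the line dominating
the spectrum (ratio 0.94) and engages the full order-12 notch. Detection
then recovers essentially every scheduled beat (390 of 396; the first few
fall in the causal startup second before the filter engages). The 0.1 Hz
interval modulation lands almost entirely in the LF band, as constructed.
Against the ground-truth schedule as "reference instrument", the detected
heart rate shows zero bias with ±0.25 bpm limits of agreement, and the
signed-rank test finds no systematic shift (p = 0.91).

Device-side utilities follow the same printed-spec arithmetic, e.g.
`estimate_lifetime(235, 4)` gives `58.75` hours for a 235 mAh cell at a
4 mA average draw.

A complete deterministic session (device simulation → burst logs →
filtering → reports on disk) is one call:

```r
res <- run_session(session_config("ECG", duration = 600, fs = 1000, seed = 1),
                   "out_dir")
```

and a thin CLI over the same functions lives at
`inst/cli/wearbiosig.R` (subcommands `synth`, `afe`, `filter-stream`,
`ecg-analyze`, `emg-analyze`, `agree`, `run-session`).

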