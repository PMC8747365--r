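Package: wearbiosig
Title: Wearable ECG/EMG Telemetry Simulation, Adaptive Powerline
    Filtering, and Biosignal Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the signal path of a wearable single-channel
    ECG/EMG monitor and implements its host-side processing chain.
    Includes ground-truthed synthetic signal generation (PQRST-morphology
    ECG from a beat schedule, band-limited stochastic EMG with activation
    envelopes, mains interference and baseline wander), a digital model of
    the device analog front-end (second-order Butterworth band limiting,
    twin-T-equivalent notch, mid-rise ADC quantization, 24 ms burst
    packetization), adaptive powerline-interference removal whose IIR
    notch order is chosen from periodic FFT-based noise assessment,
    gradient-threshold R-peak detection with time- and frequency-domain
    heart-rate-variability metrics, rectified/RMS surface-EMG intensity
    quantification, and Bland-Altman plus Wilcoxon signed-rank method
    agreement statistics.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
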