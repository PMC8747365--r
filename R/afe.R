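#' Analog front-end configuration
#'
#' Digital model of the device's acquisition chain: 2nd-order high-pass,
#' amplified 2nd-order low-pass, optional twin-T-equivalent notch, and a
#' mid-rise ADC sampling at 10 kSps. Channel defaults follow the device
#' datasheet-style specification: ECG band 0.34--41 Hz, EMG band
#' 40.17--727 Hz, total gain 1100 V/V, 8-bit ADC (8--12 supported).
#'
#' @param channel \code{"ECG"} or \code{"EMG"}.
#' @param hp_cutoff high-pass -3 dB cutoff in Hz (channel default).
#' @param lp_cutoff low-pass -3 dB cutoff in Hz (channel default).
#' @param total_gain mid-band voltage gain (V/V).
#' @param notch_f0 analog notch center frequency in Hz.
#' @param notch_enabled logical.
#' @param notch_q notch quality factor.
#' @param fs ADC sampling rate in Hz.
#' @param adc_bits ADC resolution, 8--12 bits.
#' @param adc_full_scale two-element ADC input range in the signal's
#'   amplitude units (default -1650..1650 mV, i.e. a 3.3 V span centered
#'   on the mid-scale reference level).
#' @param gain_derating scalar in (0, 1] modelling the small dual-channel
#'   loading loss (< 10\%); default 1 (no derating).
#' @return object of class \code{afe_config}.
#' @export
afe_config <- function(channel = c("ECG", "EMG"),
                       hp_cutoff = NULL, lp_cutoff = NULL,
                       total_gain = 1100, notch_f0 = 60,
                       notch_enabled = TRUE, notch_q = 5,
                       fs = 10000, adc_bits = 8L,
                       adc_full_scale = c(-1650, 1650),
                       gain_derating = 1.0) {
  channel <- match.arg(channel)
  if (is.null(hp_cutoff)) hp_cutoff <- if (channel == "ECG") 0.34 else 40.17
  if (is.null(lp_cutoff)) lp_cutoff <- if (channel == "ECG") 41 else 727
  stopifnot(hp_cutoff > 0, hp_cutoff < lp_cutoff, lp_cutoff < fs / 2,
            total_gain > 0, adc_bits >= 8, adc_bits <= 12,
            length(adc_full_scale) == 2L,
            adc_full_scale[2] > adc_full_scale[1],
            gain_derating > 0, gain_derating <= 1)
  structure(list(channel = channel, hp_cutoff = hp_cutoff,
                 lp_cutoff = lp_cutoff, total_gain = total_gain,
                 notch_f0 = notch_f0, notch_enabled = notch_enabled,
                 notch_q = notch_q, fs = fs, adc_bits = as.integer(adc_bits),
                 adc_full_scale = as.numeric(adc_full_scale),
                 gain_derating = gain_derating),
            class = "afe_config")
}

#' @export
print.afe_config <- function(x, ...) {
  cat(sprintf(paste0("<afe_config> %s: band %g-%g Hz, gain %g V/V, notch %s",
                     " @ %g Hz, fs %g Hz, %d-bit ADC [%g, %g]\n"),
              x$channel, x$hp_cutoff, x$lp_cutoff,
              x$total_gain * x$gain_derating,
              if (x$notch_enabled) "on" else "off",
              x$notch_f0, x$fs, x$adc_bits,
              x$adc_full_scale[1], x$adc_full_scale[2]))
  invisible(x)
}

# closed-form bilinear-transform 2nd-order Butterworth biquad
butter2_sos <- function(fc, fs, type) {
  if (fc <= 0 || fc >= fs / 2)
    stop(sprintf("cutoff %g Hz must lie in (0, fs/2 = %g)", fc, fs / 2))
  K <- tan(pi * fc / fs)
  norm <- 1 + sqrt(2) * K + K^2
  a1 <- 2 * (K^2 - 1) / norm
  a2 <- (1 - sqrt(2) * K + K^2) / norm
  if (type == "high") {
    b <- c(1, -2, 1) / norm
  } else {
    b <- K^2 * c(1, 2, 1) / norm
  }
  c(b, 1, a1, a2)
}

#' Design a second-order Butterworth high-pass biquad
#'
#' Bilinear-transform design with frequency prewarping, so the realized
#' -3 dB point falls exactly at the requested cutoff.
#'
#' @param fc cutoff frequency in Hz (0 < fc < fs/2).
#' @param fs sampling rate in Hz.
#' @return a \code{\link{filter_spec}}.
#' @export
design_biquad_highpass <- function(fc, fs) {
  filter_spec(matrix(butter2_sos(fc, fs, "high"), nrow = 1), fs,
              kind = "highpass", params = list(fc = fc, order = 2))
}

#' Design a second-order Butterworth low-pass biquad
#' @inheritParams design_biquad_highpass
#' @return a \code{\link{filter_spec}}.
#' @export
design_biquad_lowpass <- function(fc, fs) {
  filter_spec(matrix(butter2_sos(fc, fs, "low"), nrow = 1), fs,
              kind = "lowpass", params = list(fc = fc, order = 2))
}

#' Design the digital equivalent of the twin-T notch
#'
#' A standard constrained 2nd-order notch biquad (unity gain at DC and
#' Nyquist, a true transfer-function zero at f0), parameterized by center
#' frequency and quality factor. It stands in for the device's analog
#' twin-T RC network.
#'
#' @param f0 notch center frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param q quality factor (f0 / -3 dB bandwidth); default 5, which keeps
#'   the 41 Hz ECG band edge within 1 dB of unity for a 60 Hz notch.
#' @return a \code{\link{filter_spec}}.
#' @export
design_twin_t_notch <- function(f0, fs, q = 5) {
  stopifnot(f0 > 0, f0 < fs / 2, q > 0)
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  filter_spec(matrix(c(b, a), nrow = 1), fs,
              kind = "notch", params = list(f0 = f0, q = q, order = 2))
}

#' Simulate the analog front-end on a signal
#'
#' Applies the cascade high-pass -> amplified low-pass -> optional notch
#' (causal filtering, zero initial state). The signal's channel and
#' sampling rate must match the configuration.
#'
#' @param sig a \code{sampled_signal}.
#' @param cfg an \code{\link{afe_config}}.
#' @return the conditioned \code{sampled_signal} (same units, amplified).
#' @export
apply_afe <- function(sig, cfg) {
  stopifnot(inherits(sig, "sampled_signal"), inherits(cfg, "afe_config"))
  if (sig$channel != cfg$channel)
    stop(sprintf("signal channel %s does not match AFE channel %s",
                 sig$channel, cfg$channel))
  if (abs(sig$fs - cfg$fs) > 1e-9)
    stop(sprintf("signal fs %g does not match AFE fs %g (resample first)",
                 sig$fs, cfg$fs))
  hp <- design_biquad_highpass(cfg$hp_cutoff, cfg$fs)
  lp <- design_biquad_lowpass(cfg$lp_cutoff, cfg$fs)
  y <- sos_chunk(sig$x, hp$sos)$y
  y <- sos_chunk(y, lp$sos)$y * cfg$total_gain * cfg$gain_derating
  if (cfg$notch_enabled) {
    nt <- design_twin_t_notch(cfg$notch_f0, cfg$fs, cfg$notch_q)
    y <- sos_chunk(y, nt$sos)$y
  }
  replace_samples(sig, y)
}

#' Composite frequency response of the AFE cascade
#'
#' @param cfg an \code{\link{afe_config}}.
#' @param f frequencies in Hz.
#' @return complex response including the gain factor.
#' @export
afe_response <- function(cfg, f) {
  hp <- design_biquad_highpass(cfg$hp_cutoff, cfg$fs)
  lp <- design_biquad_lowpass(cfg$lp_cutoff, cfg$fs)
  H <- filter_response(hp, f) * filter_response(lp, f) *
    cfg$total_gain * cfg$gain_derating
  if (cfg$notch_enabled) {
    nt <- design_twin_t_notch(cfg$notch_f0, cfg$fs, cfg$notch_q)
    H <- H * filter_response(nt, f)
  }
  H
}

#' Mid-rise ADC quantization
#'
#' Uniform mid-rise quantizer over the configured full-scale range;
#' out-of-range samples clip to the edge codes and are counted.
#'
#' @param sig a \code{sampled_signal} (amplitudes in the same units as
#'   \code{cfg$adc_full_scale}).
#' @param cfg an \code{\link{afe_config}}.
#' @return integer vector of codes in [0, 2^bits - 1] with attributes
#'   \code{n_clipped}, \code{lsb}, \code{lo}, \code{bits}, \code{fs},
#'   \code{mode}.
#' @export
quantize <- function(sig, cfg) {
  stopifnot(inherits(sig, "sampled_signal"), inherits(cfg, "afe_config"))
  lo <- cfg$adc_full_scale[1]
  hi <- cfg$adc_full_scale[2]
  nlev <- 2L^cfg$adc_bits
  lsb <- (hi - lo) / nlev
  codes <- floor((sig$x - lo) / lsb)
  n_clipped <- sum(sig$x < lo | sig$x > hi)
  codes <- pmin(pmax(codes, 0), nlev - 1L)
  structure(as.integer(codes), n_clipped = n_clipped, lsb = lsb, lo = lo,
            bits = cfg$adc_bits, fs = cfg$fs, mode = sig$channel)
}

#' Reconstruct a signal from ADC codes
#'
#' Mid-rise inverse: code k maps to lo + (k + 0.5) * LSB, giving at most
#' half-LSB reconstruction error for in-range samples.
#'
#' @param codes integer codes as produced by \code{\link{quantize}} (or a
#'   plain integer vector, with \code{cfg} supplying the geometry).
#' @param cfg an \code{\link{afe_config}}.
#' @param t0 time of the first sample.
#' @return a \code{sampled_signal}.
#' @export
dequantize <- function(codes, cfg, t0 = 0) {
  lo <- cfg$adc_full_scale[1]
  lsb <- (cfg$adc_full_scale[2] - lo) / 2L^cfg$adc_bits
  mode <- attr(codes, "mode")
  if (is.null(mode)) mode <- cfg$channel
  sampled_signal(lo + (as.numeric(codes) + 0.5) * lsb, fs = cfg$fs,
                 units = "mV", channel = mode, t0 = t0)
}

#' Packetize ADC codes into 24 ms telemetry bursts
#'
#' Splits a code stream into frames of \code{fs * 0.024} samples (240 at
#' 10 kSps), the buffer size the device radio transmits at a time. A
#' trailing partial frame is zero-padded and flagged with the pad count.
#'
#' @param codes integer code vector.
#' @param fs sampling rate in Hz; \code{fs * 0.024} must be integral.
#' @param mode \code{"ECG"} or \code{"EMG"}.
#' @param t0 time of the first sample in seconds.
#' @return list of \code{packet_burst} objects (fields \code{seq},
#'   \code{mode}, \code{samples}, \code{t_start}, \code{partial},
#'   \code{n_pad}).
#' @export
packetize <- function(codes, fs, mode = c("ECG", "EMG"), t0 = 0) {
  mode <- match.arg(mode)
  spb <- fs * 0.024
  if (abs(spb - round(spb)) > 1e-9)
    stop(sprintf("fs * 24 ms = %g is not an integral samples-per-burst", spb))
  spb <- as.integer(round(spb))
  n <- length(codes)
  if (n == 0L) return(list())
  nb <- ceiling(n / spb)
  out <- vector("list", nb)
  for (k in seq_len(nb)) {
    i0 <- (k - 1L) * spb + 1L
    i1 <- min(k * spb, n)
    s <- as.integer(codes[i0:i1])
    n_pad <- spb - length(s)
    if (n_pad > 0L) s <- c(s, integer(n_pad))
    out[[k]] <- structure(list(seq = k - 1L, mode = mode, samples = s,
                               t_start = t0 + (i0 - 1L) / fs,
                               partial = n_pad > 0L, n_pad = n_pad),
                          class = "packet_burst")
  }
  out
}

#' Reassemble a code stream from telemetry bursts
#'
#' Exact inverse of \code{\link{packetize}}: pad samples of flagged
#' partial frames are dropped, so the round trip reproduces the input
#' codes exactly.
#'
#' @param bursts list of \code{packet_burst} objects in sequence order.
#' @return integer code vector.
#' @export
depacketize <- function(bursts) {
  if (length(bursts) == 0L) return(integer(0))
  seqs <- vapply(bursts, function(b) b$seq, numeric(1))
  if (any(diff(seqs) != 1))
    stop("burst sequence numbers are not contiguous")
  unlist(lapply(bursts, function(b) {
    s <- b$samples
    if (b$n_pad > 0L) s[seq_len(length(s) - b$n_pad)] else s
  }))
}

#' Battery lifetime from capacity and average current draw
#'
#' @param capacity_mah battery capacity in mAh.
#' @param avg_current_ma average current draw in mA.
#' @return lifetime in hours.
#' @examples
#' estimate_lifetime(235, 4)  # 58.75 h on a 235 mAh button cell at 4 mA
#' @export
estimate_lifetime <- function(capacity_mah, avg_current_ma) {
  if (capacity_mah <= 0 || avg_current_ma <= 0)
    stop("capacity and average current must both be positive")
  capacity_mah / avg_current_ma
}
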