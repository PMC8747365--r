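#' Beat schedule: ground-truth R-peak times
#'
#' Constructs the sequence of true beat (R-peak) times that drives the
#' synthetic ECG generator and later serves as the oracle for detector
#' validation. Beat-to-beat variability can be imposed either as a
#' sinusoidal modulation of the R-R interval (emulating respiratory sinus
#' arrhythmia / autonomic modulation at a chosen frequency) or as i.i.d.
#' Gaussian jitter.
#'
#' @param duration session length in seconds (beats are laid until this time).
#' @param mean_hr mean heart rate in beats per minute.
#' @param hrv optional modulation spec: either
#'   \code{list(type = "sinusoidal", freq = Hz, depth_ms = peak deviation)}
#'   or \code{list(type = "jitter", sd_ms = SD of i.i.d. interval jitter)}.
#' @param seed RNG seed (used only for jitter-type variability).
#' @param beat_times directly supply beat times (seconds, strictly
#'   increasing); overrides generation. \code{mean_hr} is then derived.
#' @return An object of class \code{beat_schedule} with fields
#'   \code{beat_times}, \code{mean_hr}, \code{hrv_profile}.
#' @export
beat_schedule <- function(duration = NULL, mean_hr = 60, hrv = NULL,
                          seed = NULL, beat_times = NULL) {
  if (is.null(beat_times)) {
    stopifnot(is.numeric(duration), duration > 0, mean_hr > 0)
    base <- 60 / mean_hr
    if (is.null(hrv)) {
      beat_times <- seq(base, duration, by = base)
    } else if (identical(hrv$type, "sinusoidal")) {
      depth <- hrv$depth_ms / 1000
      fmod <- hrv$freq
      beat_times <- numeric(0)
      t <- base
      while (t <= duration) {
        beat_times <- c(beat_times, t)
        t <- t + base + depth * sin(2 * pi * fmod * t)
      }
    } else if (identical(hrv$type, "jitter")) {
      n_max <- ceiling(duration / base * 1.5) + 10L
      jit <- with_seed(seed, stats::rnorm(n_max, 0, hrv$sd_ms / 1000))
      ivs <- pmax(base + jit, 0.25)
      beat_times <- cumsum(ivs)
      beat_times <- beat_times[beat_times <= duration]
    } else stop("unknown hrv profile type: ", hrv$type)
  }
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) == 0L) stop("schedule is empty")
  if (is.unsorted(beat_times, strictly = TRUE))
    stop("beat_times must be strictly increasing")
  ivs <- diff(beat_times)
  if (any(ivs <= 0.2))
    stop("beat intervals must exceed the 0.2 s physiological refractory floor")
  structure(list(beat_times = beat_times,
                 mean_hr = if (length(ivs)) mean(60 / ivs) else 60 / beat_times[1],
                 hrv_profile = hrv),
            class = "beat_schedule")
}

#' @export
print.beat_schedule <- function(x, ...) {
  cat(sprintf("<beat_schedule> %d beats over %.1f s, mean HR %.1f bpm\n",
              length(x$beat_times), max(x$beat_times), x$mean_hr))
  invisible(x)
}

#' PQRST morphology parameters for the synthetic ECG
#'
#' The synthetic ECG is a sum of five Gaussian deflections (P, Q, R, S, T)
#' per beat, positioned relative to the R-peak of a 1-second reference
#' beat. Amplitudes are in mV, widths (Gaussian sigma) and offsets in
#' seconds. By default the template time axis is scaled linearly with the
#' local R-R interval so that fast schedules stay physiologically
#' non-overlapping.
#'
#' @param amplitudes named numeric vector (mV) for P, Q, R, S, T.
#' @param offsets named numeric vector (s), deflection centers relative to R.
#' @param widths named numeric vector (s), Gaussian sigmas (> 0).
#' @param scale_with_rr logical; scale offsets and widths by the local R-R
#'   interval (reference 1 s). When FALSE the template is fixed and
#'   schedules whose intervals are shorter than the template support are
#'   rejected.
#' @return list of class \code{ecg_morphology}.
#' @export
ecg_morphology <- function(amplitudes = c(P = 0.15, Q = -0.10, R = 1.00,
                                          S = -0.15, T = 0.30),
                           offsets = c(P = -0.20, Q = -0.030, R = 0,
                                       S = 0.030, T = 0.25),
                           widths = c(P = 0.025, Q = 0.010, R = 0.012,
                                      S = 0.010, T = 0.045),
                           scale_with_rr = TRUE) {
  stopifnot(all(widths > 0), length(amplitudes) == length(offsets),
            length(offsets) == length(widths))
  structure(list(amplitudes = amplitudes, offsets = offsets, widths = widths,
                 scale_with_rr = scale_with_rr),
            class = "ecg_morphology")
}

#' Generate a synthetic ECG from a beat schedule
#'
#' Renders a sum-of-Gaussians PQRST waveform at each scheduled beat time
#' and returns both the signal and the exact schedule used, which
#' downstream tests treat as ground truth.
#'
#' @param schedule a \code{\link{beat_schedule}}.
#' @param fs sampling rate in Hz (>= 500).
#' @param morphology an \code{\link{ecg_morphology}}.
#' @param duration signal length in seconds; default last beat + 0.5 s.
#' @return list with elements \code{signal} (a \code{sampled_signal}, mV)
#'   and \code{schedule} (the input, unchanged).
#' @export
generate_ecg <- function(schedule, fs, morphology = ecg_morphology(),
                         duration = NULL) {
  stopifnot(inherits(schedule, "beat_schedule"),
            inherits(morphology, "ecg_morphology"))
  if (fs < 500) stop("fs must be >= 500 Hz for ECG synthesis")
  bt <- schedule$beat_times
  if (is.null(duration)) duration <- max(bt) + 0.5
  n <- round(duration * fs)
  x <- numeric(n)
  # local R-R interval per beat: min of adjacent intervals, reference 1 s
  ivs <- diff(bt)
  local_rr <- if (length(bt) == 1L) 1 else {
    prev <- c(ivs[1], ivs)
    nxt <- c(ivs, ivs[length(ivs)])
    pmin(prev, nxt)
  }
  support <- max(abs(morphology$offsets) + 4 * morphology$widths)
  if (!morphology$scale_with_rr && length(ivs) &&
      min(ivs) < support)
    stop(sprintf(paste0("overlapping beats: minimum interval %.3f s is ",
                        "shorter than the waveform support %.3f s; shorten ",
                        "the template or enable scale_with_rr"),
                 min(ivs), support))
  scl <- if (morphology$scale_with_rr)
    pmin(pmax(local_rr, 0.2), 1.2) else rep(1, length(bt))
  for (k in seq_along(bt)) {
    for (j in seq_along(morphology$amplitudes)) {
      mu <- bt[k] + morphology$offsets[j] * scl[k]
      sg <- morphology$widths[j] * scl[k]
      i0 <- max(1L, floor((mu - 4 * sg) * fs) + 1L)
      i1 <- min(n, ceiling((mu + 4 * sg) * fs) + 1L)
      if (i0 > i1) next
      tt <- (seq(i0, i1) - 1L) / fs
      x[i0:i1] <- x[i0:i1] +
        morphology$amplitudes[j] * exp(-(tt - mu)^2 / (2 * sg^2))
    }
  }
  sig <- sampled_signal(x, fs, units = "mV", channel = "ECG",
                        meta = list(generator = "pqrst_sum_of_gaussians",
                                    mean_hr = schedule$mean_hr))
  list(signal = sig, schedule = schedule)
}

#' EMG activation profile
#'
#' Piecewise-constant activation level in [0, 1] over time, with the
#' carrier band and full-activation amplitude of the stochastic surface-EMG
#' model.
#'
#' @param times breakpoint times in seconds (first must be 0, increasing).
#' @param levels activation level on each interval, in [0, 1]; level i
#'   applies on [times[i], times[i+1]) and the last until the end.
#' @param duration total profile duration in seconds.
#' @param carrier_band two-element band in Hz (default 20--450).
#' @param carrier_sd RMS amplitude (mV) of the carrier at full activation.
#' @return object of class \code{emg_activation}.
#' @export
emg_activation <- function(times = 0, levels = 1, duration,
                           carrier_band = c(20, 450), carrier_sd = 0.1) {
  stopifnot(length(times) == length(levels), times[1] == 0,
            !is.unsorted(times, strictly = TRUE),
            all(levels >= 0), all(levels <= 1),
            duration > max(times), length(carrier_band) == 2L,
            carrier_band[1] > 0, carrier_band[2] > carrier_band[1],
            carrier_sd >= 0)
  structure(list(times = times, levels = levels, duration = duration,
                 carrier_band = carrier_band, carrier_sd = carrier_sd),
            class = "emg_activation")
}

#' Evaluate an activation envelope at given times
#' @param profile an \code{\link{emg_activation}}.
#' @param t times in seconds.
#' @return activation level in [0,1] at each time.
#' @export
activation_at <- function(profile, t) {
  idx <- findInterval(t, profile$times)
  idx[idx < 1L] <- 1L
  profile$levels[idx]
}

#' Generate synthetic surface EMG
#'
#' Band-limited Gaussian noise (zero-phase band-pass-shaped, normalized to
#' unit RMS) amplitude-modulated by the activation envelope, so that the
#' windowed RMS of the output tracks \code{envelope * carrier_sd}.
#'
#' @param profile an \code{\link{emg_activation}}.
#' @param fs sampling rate in Hz; must exceed twice the upper carrier edge.
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @return list with \code{signal} (a \code{sampled_signal}, mV) and
#'   \code{profile} (the input, unchanged).
#' @export
generate_emg <- function(profile, fs, seed = 1L) {
  stopifnot(inherits(profile, "emg_activation"))
  if (fs <= 2 * profile$carrier_band[2])
    stop(sprintf("carrier band upper edge %g Hz is at or above Nyquist (fs=%g)",
                 profile$carrier_band[2], fs))
  n <- round(profile$duration * fs)
  tt <- (seq_len(n) - 1L) / fs
  env <- activation_at(profile, tt)
  if (all(env == 0) || profile$carrier_sd == 0) {
    x <- numeric(n)
  } else {
    white <- with_seed(seed, stats::rnorm(n))
    bp <- signal::butter(2, profile$carrier_band / (fs / 2), type = "pass")
    carrier <- signal::filtfilt(bp, white)
    carrier <- carrier / stats::sd(carrier)
    x <- profile$carrier_sd * env * carrier
  }
  sig <- sampled_signal(x, fs, units = "mV", channel = "EMG",
                        meta = list(generator = "bandlimited_gaussian_emg",
                                    seed = seed))
  list(signal = sig, profile = profile)
}

#' Mains interference specification
#'
#' Deterministic mains fundamental plus harmonics, slow sinusoidal
#' baseline wander, and seeded broadband Gaussian noise — the additive
#' contamination model for indoor recordings near wall power.
#'
#' @param mains_freq mains frequency in Hz; 50 or 60 unless
#'   \code{strict = FALSE}.
#' @param harmonic_amplitudes amplitudes (mV) of the fundamental and
#'   successive harmonics (element k is the amplitude at k * mains_freq).
#' @param baseline_wander \code{list(amplitude = mV, freq = Hz)} with
#'   freq < 0.5 Hz, or NULL for none.
#' @param broadband_noise_sd SD (mV) of added white Gaussian noise.
#' @param strict validate mains_freq in \{50, 60\}.
#' @return object of class \code{interference_spec}.
#' @export
interference_spec <- function(mains_freq = 60, harmonic_amplitudes = 0.5,
                              baseline_wander = NULL,
                              broadband_noise_sd = 0, strict = TRUE) {
  if (strict && !mains_freq %in% c(50, 60))
    stop("mains_freq must be 50 or 60 Hz (use strict = FALSE to override)")
  stopifnot(all(harmonic_amplitudes >= 0), broadband_noise_sd >= 0)
  if (!is.null(baseline_wander)) {
    stopifnot(baseline_wander$amplitude >= 0, baseline_wander$freq > 0,
              baseline_wander$freq < 0.5)
  }
  structure(list(mains_freq = mains_freq,
                 harmonic_amplitudes = harmonic_amplitudes,
                 baseline_wander = baseline_wander,
                 broadband_noise_sd = broadband_noise_sd),
            class = "interference_spec")
}

#' Add interference to a signal
#'
#' @param sig a \code{sampled_signal}.
#' @param spec an \code{\link{interference_spec}}.
#' @param seed RNG seed for the broadband noise term.
#' @return the contaminated \code{sampled_signal}.
#' @export
add_interference <- function(sig, spec, seed = 1L) {
  stopifnot(inherits(sig, "sampled_signal"), inherits(spec, "interference_spec"))
  if (length(sig$x) == 0L) stop("signal is empty")
  tt <- signal_times(sig)
  x <- sig$x
  for (k in seq_along(spec$harmonic_amplitudes)) {
    a <- spec$harmonic_amplitudes[k]
    if (a > 0) x <- x + a * sin(2 * pi * k * spec$mains_freq * tt)
  }
  if (!is.null(spec$baseline_wander) && spec$baseline_wander$amplitude > 0) {
    x <- x + spec$baseline_wander$amplitude *
      sin(2 * pi * spec$baseline_wander$freq * tt)
  }
  if (spec$broadband_noise_sd > 0) {
    x <- x + with_seed(seed,
                       stats::rnorm(length(x), 0, spec$broadband_noise_sd))
  }
  replace_samples(sig, x)
}
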