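#' Full-wave rectification
#'
#' @param sig an EMG \code{sampled_signal} (or numeric vector).
#' @return the rectified signal (elementwise absolute value).
#' @export
rectify <- function(sig) {
  if (inherits(sig, "sampled_signal")) replace_samples(sig, abs(sig$x))
  else abs(sig)
}

#' Windowed RMS and integrated EMG
#'
#' Per window: rms = sqrt(mean(x^2)) and the classical integrated EMG
#' (iEMG), the rectified-signal sum times the sample period (mV.s).
#' Non-overlapping when \code{hop == window}.
#'
#' @param sig an EMG \code{sampled_signal}.
#' @param window window length in seconds (default 0.2, i.e. 200 ms);
#'   \code{window * fs} must be >= 2 samples and <= signal length.
#' @param hop hop between window starts in seconds (default = window).
#' @return object of class \code{emg_intensity}: a data.frame with columns
#'   \code{t_mid} (s), \code{rms} (mV), \code{integrated} (mV.s);
#'   attributes \code{window}, \code{hop}, \code{fs}.
#' @export
windowed_rms <- function(sig, window = 0.2, hop = window) {
  stopifnot(inherits(sig, "sampled_signal"))
  fs <- sig$fs
  wn <- as.integer(round(window * fs))
  hn <- max(1L, as.integer(round(hop * fs)))
  if (wn < 2L) stop("window must cover at least 2 samples")
  n <- length(sig$x)
  if (wn > n) stop(sprintf("window (%d samples) longer than signal (%d)", wn, n))
  starts <- seq(1L, n - wn + 1L, by = hn)
  cs2 <- cumsum(c(0, sig$x^2))
  csa <- cumsum(c(0, abs(sig$x)))
  rms <- sqrt((cs2[starts + wn] - cs2[starts]) / wn)
  integ <- (csa[starts + wn] - csa[starts]) / fs
  out <- data.frame(t_mid = sig$t0 + (starts - 1L + wn / 2) / fs,
                    rms = rms, integrated = integ)
  structure(out, window = window, hop = hop, fs = fs,
            class = c("emg_intensity", "data.frame"))
}

#' EMG linear envelope
#'
#' Rectification followed by a low-pass (default 2nd-order Butterworth at
#' 5 Hz). In offline mode the low-pass is applied zero-phase
#' (forward-backward), so the envelope is not delayed with respect to the
#' activation.
#'
#' @param sig an EMG \code{sampled_signal} (raw or already rectified).
#' @param cutoff low-pass cutoff in Hz (default 5; must be < fs/2).
#' @param zero_phase logical, default TRUE (offline zero-phase filtering);
#'   FALSE gives the causal single-pass filter.
#' @return the envelope as a \code{sampled_signal} (non-negative up to
#'   filter ringing, clamped at 0).
#' @export
emg_envelope <- function(sig, cutoff = 5, zero_phase = TRUE) {
  stopifnot(inherits(sig, "sampled_signal"))
  if (cutoff >= sig$fs / 2)
    stop(sprintf("envelope cutoff %g Hz must be below Nyquist (%g Hz)",
                 cutoff, sig$fs / 2))
  r <- abs(sig$x)
  lp <- design_biquad_lowpass(cutoff, sig$fs)
  y <- if (zero_phase) {
    signal::filtfilt(signal::Arma(b = lp$sos[1, 1:3], a = lp$sos[1, 4:6]), r)
  } else {
    sos_chunk(r, lp$sos)$y
  }
  replace_samples(sig, pmax(y, 0))
}

#' Normalized long-horizon intensity
#'
#' Averages the windowed RMS over long windows (default 30 min) and
#' normalizes by the session maximum, so values lie in [0, 1] with the
#' most active window at exactly 1. An all-zero session yields all zeros
#' (defined behavior, not an error).
#'
#' @param series an \code{emg_intensity} from \code{\link{windowed_rms}}.
#' @param long_window long averaging window in seconds (default 1800).
#' @return data.frame with \code{t_mid} (s), \code{mean_rms} (mV),
#'   \code{normalized} in [0, 1].
#' @export
normalized_intensity <- function(series, long_window = 1800) {
  stopifnot(inherits(series, "emg_intensity"))
  span <- max(series$t_mid) - min(series$t_mid)
  if (span < long_window)
    stop(sprintf("session spans %.1f s; at least one long window (%g s) required",
                 span, long_window))
  t0 <- min(series$t_mid)
  idx <- floor((series$t_mid - t0) / long_window)
  means <- tapply(series$rms, idx, mean)
  t_mid <- t0 + (as.numeric(names(means)) + 0.5) * long_window
  mx <- max(means)
  data.frame(t_mid = t_mid, mean_rms = as.numeric(means),
             normalized = if (mx > 0) as.numeric(means) / mx
                          else rep(0, length(means)))
}
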