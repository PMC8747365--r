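#' Detect R-peaks by gradient thresholding
#'
#' The detection pipeline: first difference (gradient) of the waveform ->
#' moving-average smoothing -> adaptive amplitude threshold on the
#' smoothed absolute gradient (a fraction of a rolling statistic over a
#' trailing baseline window) -> refractory suppression -> peak
#' localization at the local signal maximum near each threshold crossing.
#' Deterministic.
#'
#' @param sig an ECG \code{sampled_signal}, fs >= 250 Hz, duration >= 2 s.
#' @param threshold_frac threshold as a fraction of the rolling gradient
#'   statistic (default 0.4).
#' @param smooth_window gradient smoothing window in seconds (default 25 ms).
#' @param refractory minimum peak separation in seconds (default 0.2).
#' @param baseline_window trailing window for the rolling statistic in
#'   seconds (default 5).
#' @param stat_quantile quantile of the smoothed absolute gradient used as
#'   the rolling statistic; default 1 (rolling maximum).
#' @param amp_gate minimum ratio of peak height (above the local median)
#'   to the local RMS; candidates below it are rejected as noise
#'   (default 3.5, set 0 to disable).
#' @return object of class \code{rpeak_series}: \code{peak_times} (s),
#'   \code{peak_indices}, \code{detector_params}.
#' @export
detect_r_peaks <- function(sig, threshold_frac = 0.4, smooth_window = 0.025,
                           refractory = 0.2, baseline_window = 5,
                           stat_quantile = 1, amp_gate = 3.5) {
  stopifnot(inherits(sig, "sampled_signal"))
  if (sig$channel != "ECG") stop("R-peak detection expects an ECG channel")
  if (sig$fs < 250) stop("fs must be >= 250 Hz")
  if (signal_duration(sig) < 2) stop("signal must span at least 2 s")
  fs <- sig$fs
  x <- sig$x
  n <- length(x)
  params <- list(threshold_frac = threshold_frac, smooth_window = smooth_window,
                 refractory = refractory, baseline_window = baseline_window,
                 stat_quantile = stat_quantile, amp_gate = amp_gate)
  empty <- structure(list(peak_times = numeric(0), peak_indices = integer(0),
                          detector_params = params), class = "rpeak_series")
  g <- c(0, diff(x)) * fs
  a <- abs(moving_average(g, round(smooth_window * fs)))
  if (max(a) == 0) return(empty)

  # rolling statistic per 1 s block over the trailing baseline window
  fsb <- as.integer(round(fs))
  blk <- as.integer(ceiling(seq_len(n) / fsb))
  nblk <- max(blk)
  nb_back <- max(1L, as.integer(round(baseline_window)))
  blk_stat <- numeric(nblk)
  for (s in seq_len(nblk)) {
    lo <- (max(1L, s - nb_back + 1L) - 1L) * fsb + 1L
    hi <- min(n, s * fsb)
    blk_stat[s] <- if (stat_quantile >= 1) max(a[lo:hi]) else
      stats::quantile(a[lo:hi], stat_quantile, names = FALSE)
  }
  thr <- threshold_frac * blk_stat[blk]

  above <- a > thr & thr > 0
  if (!any(above)) return(empty)
  d <- diff(c(0L, as.integer(above), 0L))
  run_start <- which(d == 1L)
  run_end <- which(d == -1L) - 1L

  look <- round(0.05 * fs)
  cand_idx <- integer(length(run_start))
  for (r in seq_along(run_start)) {
    imax <- run_start[r] + which.max(a[run_start[r]:run_end[r]]) - 1L
    w0 <- max(1L, imax - look)
    w1 <- min(n, imax + look)
    cand_idx[r] <- w0 + which.max(x[w0:w1]) - 1L
  }
  cand_idx <- unique(cand_idx)

  # amplitude gate against the local background
  if (amp_gate > 0) {
    keep <- vapply(cand_idx, function(i) {
      lo <- max(1L, i - as.integer(baseline_window * fs))
      seg <- x[lo:min(n, i + look)]
      med <- stats::median(seg)
      rms <- sqrt(mean((seg - med)^2))
      rms > 0 && (x[i] - med) >= amp_gate * rms
    }, logical(1))
    cand_idx <- cand_idx[keep]
  }
  if (length(cand_idx) == 0L) return(empty)

  # refractory suppression: keep the taller of any pair closer than refractory
  cand_idx <- sort(cand_idx)
  ref_n <- round(refractory * fs)
  kept <- cand_idx[1]
  for (i in cand_idx[-1]) {
    last <- kept[length(kept)]
    if (i - last >= ref_n) {
      kept <- c(kept, i)
    } else if (x[i] > x[last]) {
      kept[length(kept)] <- i
    }
  }
  structure(list(peak_times = sig$t0 + (kept - 1L) / fs,
                 peak_indices = kept, detector_params = params),
            class = "rpeak_series")
}

#' @export
print.rpeak_series <- function(x, ...) {
  cat(sprintf("<rpeak_series> %d peaks\n", length(x$peak_times)))
  invisible(x)
}

#' R-R intervals from detected peaks
#'
#' @param peaks an \code{rpeak_series} (or a numeric vector of peak times
#'   in seconds) with at least 2 peaks.
#' @return object of class \code{rr_series}: \code{intervals} (ms, one per
#'   consecutive peak pair) and \code{t_mid} (s, interval midpoints).
#' @export
rr_intervals <- function(peaks) {
  pt <- if (inherits(peaks, "rpeak_series")) peaks$peak_times else as.numeric(peaks)
  if (length(pt) < 2L) stop("at least 2 peaks are required to form intervals")
  iv <- diff(pt) * 1000
  structure(list(intervals = iv, t_mid = (pt[-1] + pt[-length(pt)]) / 2),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d intervals, mean %.1f ms\n",
              length(x$intervals), mean(x$intervals)))
  invisible(x)
}

#' Windowed average heart rate
#'
#' Average BPM per fixed window of the session: bpm = 60000 / mean(R-R
#' intervals in window). Windows with fewer than 2 intervals are flagged
#' missing (NA).
#'
#' @param rr an \code{rr_series}.
#' @param window window length in seconds (default 1800, i.e. 30 min).
#' @param hop hop between window starts (default = window, non-overlapping).
#' @return data.frame with \code{t_mid} (window mid-time, s), \code{bpm},
#'   \code{n_intervals}, \code{missing}.
#' @export
windowed_bpm <- function(rr, window = 1800, hop = window) {
  stopifnot(inherits(rr, "rr_series"))
  if (length(rr$intervals) == 0L) stop("empty R-R series")
  span <- max(rr$t_mid) - min(rr$t_mid)
  if (span < window)
    stop(sprintf("R-R series spans %.1f s; at least one full window (%g s) required",
                 span, window))
  starts <- seq(min(rr$t_mid), max(rr$t_mid) - window + 1e-9, by = hop)
  out <- lapply(starts, function(s) {
    sel <- rr$t_mid >= s & rr$t_mid < s + window
    k <- sum(sel)
    data.frame(t_mid = s + window / 2,
               bpm = if (k >= 2L) 60000 / mean(rr$intervals[sel]) else NA_real_,
               n_intervals = k, missing = k < 2L)
  })
  do.call(rbind, out)
}

#' Time-domain HRV: SDNN and RMSSD
#'
#' SDNN is the sample standard deviation (n-1 denominator) of the
#' intervals; RMSSD the root mean square of successive interval
#' differences. Both in milliseconds.
#'
#' @param rr an \code{rr_series} with at least 2 intervals.
#' @return list with \code{sdnn} and \code{rmssd} (ms).
#' @export
hrv_time <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  if (length(rr$intervals) < 2L)
    stop("at least 2 intervals (3 peaks) are required for SDNN/RMSSD")
  list(sdnn = stats::sd(rr$intervals),
       rmssd = sqrt(mean(diff(rr$intervals)^2)))
}

#' Normalized-unit summary of LF and HF band powers
#'
#' The normalized-unit convention used by the frequency-domain HRV
#' report: each band as a percentage of (LF + HF), and their ratio.
#'
#' @param lf_power low-frequency band power.
#' @param hf_power high-frequency band power.
#' @return list \code{lf_nu}, \code{hf_nu} (summing to 100), \code{lf_hf}.
#' @export
normalized_band_units <- function(lf_power, hf_power) {
  tot <- lf_power + hf_power
  if (tot <= 0) stop("LF + HF power must be positive")
  list(lf_nu = 100 * lf_power / tot,
       hf_nu = 100 * hf_power / tot,
       lf_hf = if (hf_power > 0) lf_power / hf_power else Inf)
}

#' Frequency-domain HRV: LF/HF analysis of the tachogram
#'
#' Evenly resamples the R-R interval tachogram (cubic spline, default
#' 4 Hz), removes a linear trend, estimates the PSD by Welch's method and
#' integrates the low-frequency (0.04--0.15 Hz) and high-frequency
#' (0.15--0.4 Hz) bands. Reported in normalized units:
#' lf_nu = 100 LF/(LF+HF), hf_nu = 100 HF/(LF+HF), lf_hf = LF/HF.
#'
#' @param rr an \code{rr_series} spanning at least 5 minutes.
#' @param bands list with elements \code{lf} and \code{hf}, each a 2-vector
#'   of Hz.
#' @param resample_rate tachogram resampling rate in Hz (default 4).
#' @return object of class \code{hrv_report}: \code{lf_power},
#'   \code{hf_power} (ms^2), \code{lf_nu}, \code{hf_nu}, \code{lf_hf},
#'   \code{band_definitions}.
#' @export
hrv_freq <- function(rr, bands = list(lf = c(0.04, 0.15), hf = c(0.15, 0.4)),
                     resample_rate = 4) {
  stopifnot(inherits(rr, "rr_series"))
  span <- max(rr$t_mid) - min(rr$t_mid)
  if (span < 300)
    stop(sprintf("R-R series spans %.1f s; >= 300 s required for LF/HF analysis",
                 span))
  tg <- seq(min(rr$t_mid), max(rr$t_mid), by = 1 / resample_rate)
  ivs <- stats::spline(rr$t_mid, rr$intervals, xout = tg, method = "fmm")$y
  ivs <- stats::resid(stats::lm(ivs ~ tg))
  nper <- min(length(ivs), 256L * max(1L, as.integer(round(resample_rate / 4))))
  psd <- welch_psd(ivs, resample_rate, nperseg = nper)
  lf <- band_power(psd, bands$lf[1], bands$lf[2])
  hf <- band_power(psd, bands$hf[1], bands$hf[2])
  nu <- normalized_band_units(lf, hf)
  structure(list(lf_power = lf, hf_power = hf, lf_nu = nu$lf_nu,
                 hf_nu = nu$hf_nu, lf_hf = nu$lf_hf,
                 band_definitions = bands),
            class = "hrv_report")
}

#' @export
print.hrv_report <- function(x, ...) {
  cat(sprintf("<hrv_report> LF %.1f nu, HF %.1f nu, LF/HF %.2f\n",
              x$lf_nu, x$hf_nu, x$lf_hf))
  invisible(x)
}
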