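#' Adaptive filtering policy
#'
#' Parameters of the host-side noise management loop: how often the mains
#' interference level is re-assessed by FFT, the analysis window it looks
#' at, the spectral band counted as powerline interference (PLI), and the
#' mapping from PLI power ratio to IIR notch order (even, 0--12; 0 means
#' the filter is bypassed).
#'
#' The literal device logging granularity (24 ms) gives only ~42 Hz
#' spectral resolution at 10 kSps, which cannot isolate a 50/60 Hz line;
#' the default analysis window is therefore 1 s (set
#' \code{analysis_window = 0.024} to reproduce the literal behavior).
#'
#' @param assessment_period seconds between noise assessments (default 60,
#'   i.e. once per minute).
#' @param analysis_window seconds of trailing signal the FFT looks at.
#' @param mains_freq mains frequency in Hz (default 60).
#' @param band_halfwidth half-width in Hz of the PLI band around
#'   mains_freq (default 1).
#' @param ratio_thresholds strictly increasing vector of 6 PLI-ratio
#'   thresholds mapping to orders 2, 4, ..., 12; ratios below the first
#'   select order 0 (bypass). Default: log-spaced from 0.01 to 0.5.
#' @param reprime state priming on a coefficient swap: \code{"replay"}
#'   re-runs the trailing \code{reprime_window} seconds of input through
#'   the new filter to warm its state; \code{"reset"} zeroes the state.
#' @param reprime_window seconds of input replayed on a swap.
#' @return object of class \code{adaptive_policy}.
#' @export
adaptive_policy <- function(assessment_period = 60, analysis_window = 1,
                            mains_freq = 60, band_halfwidth = 1,
                            ratio_thresholds = NULL,
                            reprime = c("replay", "reset"),
                            reprime_window = 0.5) {
  reprime <- match.arg(reprime)
  if (is.null(ratio_thresholds))
    ratio_thresholds <- 10^seq(log10(0.01), log10(0.5), length.out = 6)
  stopifnot(length(ratio_thresholds) == 6L,
            !is.unsorted(ratio_thresholds, strictly = TRUE),
            all(ratio_thresholds > 0), all(ratio_thresholds < 1),
            assessment_period > 0, analysis_window > 0,
            band_halfwidth > 0, mains_freq > 0)
  structure(list(assessment_period = assessment_period,
                 analysis_window = analysis_window,
                 mains_freq = mains_freq,
                 band_halfwidth = band_halfwidth,
                 ratio_thresholds = ratio_thresholds,
                 reprime = reprime, reprime_window = reprime_window),
            class = "adaptive_policy")
}

#' Assess powerline interference in a signal window
#'
#' Computes the periodogram of the trailing analysis window, integrates
#' the power in the band around the mains frequency, forms the PLI power
#' ratio (PLI band power / total non-DC power) and selects the notch
#' order from the policy's threshold table. Deterministic.
#'
#' @param window a \code{sampled_signal} covering at least
#'   \code{policy$analysis_window} seconds (the trailing window is used).
#' @param policy an \code{\link{adaptive_policy}}.
#' @return object of class \code{noise_report}: \code{window_t},
#'   \code{pli_power}, \code{total_power}, \code{pli_ratio},
#'   \code{selected_order}.
#' @export
assess_noise <- function(window, policy) {
  stopifnot(inherits(window, "sampled_signal"),
            inherits(policy, "adaptive_policy"))
  need <- round(policy$analysis_window * window$fs)
  if (length(window$x) < need)
    stop(sprintf("window has %d samples; noise assessment needs >= %d (%g s at %g Hz)",
                 length(window$x), need, policy$analysis_window, window$fs))
  x <- utils::tail(window$x, need)
  x <- x - mean(x)
  n <- length(x)
  X <- stats::fft(x)
  nfreq <- n %/% 2L + 1L
  p <- Mod(X[seq_len(nfreq)])^2
  f <- (seq_len(nfreq) - 1L) * window$fs / n
  in_band <- abs(f - policy$mains_freq) <= policy$band_halfwidth
  total <- sum(p[-1])  # exclude DC
  pli <- sum(p[-1][in_band[-1]])
  ratio <- if (total > 0) pli / total else 0
  order <- pli_order(ratio, policy$ratio_thresholds)
  structure(list(window_t = policy$analysis_window, pli_power = pli,
                 total_power = total, pli_ratio = ratio,
                 selected_order = order),
            class = "noise_report")
}

# ratio -> even order in {0, 2, ..., 12} via the threshold table
pli_order <- function(ratio, thresholds) {
  2L * findInterval(ratio, thresholds)
}

#' @export
print.noise_report <- function(x, ...) {
  cat(sprintf("<noise_report> pli_ratio %.4f -> IIR order %d\n",
              x$pli_ratio, x$selected_order))
  invisible(x)
}

#' Design the adaptive IIR notch of a given order
#'
#' A cascade of order/2 identical second-order notch sections centered at
#' the mains frequency; attenuation in the mains band strictly increases
#' with order while the in-band gain stays near unity. The per-section
#' quality factor is scaled with cascade depth (\code{q * order / 2})
#' so that deeper cascades reject more without widening their bite or
#' adding group delay at QRS frequencies.
#'
#' @param order even integer in 2, 4, ..., 12 (order 0 means bypass and is
#'   handled by the caller, not here).
#' @param mains_freq notch center in Hz.
#' @param fs sampling rate in Hz.
#' @param q base quality factor (default 5).
#' @return a \code{\link{filter_spec}}.
#' @export
design_adaptive_notch <- function(order, mains_freq, fs, q = 5) {
  if (length(order) != 1L || order %% 2 != 0 || order < 2 || order > 12)
    stop("order must be an even integer in 2..12 (0 = bypass, handled by caller)")
  q_sec <- q * order / 2
  one <- design_twin_t_notch(mains_freq, fs, q_sec)
  sos <- one$sos[rep(1L, order / 2L), , drop = FALSE]
  filter_spec(sos, fs, kind = "adaptive_notch",
              params = list(f0 = mains_freq, q = q_sec, order = order))
}

#' Stream-filter a burst sequence with adaptive notch order
#'
#' Dequantizes a contiguous telemetry burst stream and runs it through the
#' host-side adaptive IIR notch. The incoming (pre-filter) signal is
#' re-assessed at the first assessment instant (once one analysis window
#' of data exists) and every \code{assessment_period} thereafter; on an
#' order change the filter coefficients are swapped with the configured
#' state-priming policy. Output is strictly causal: sample n depends only
#' on inputs up to n. Deterministic.
#'
#' @param bursts list of \code{packet_burst} objects (contiguous seq).
#' @param policy an \code{\link{adaptive_policy}}.
#' @param cfg the \code{\link{afe_config}} describing the quantization.
#' @param on_gap \code{"error"} (default) or \code{"zero_fill"}: behavior
#'   on sequence-number gaps; zero-filled spans are flagged in the result.
#' @return list with \code{signal} (filtered \code{sampled_signal}),
#'   \code{reports} (list of \code{noise_report}s, each with an extra
#'   \code{time} field), and \code{gaps} (zero-filled seq numbers).
#' @export
stream_filter <- function(bursts, policy, cfg, on_gap = c("error", "zero_fill")) {
  on_gap <- match.arg(on_gap)
  stopifnot(length(bursts) > 0, inherits(policy, "adaptive_policy"),
            inherits(cfg, "afe_config"))
  modes <- vapply(bursts, function(b) b$mode, character(1))
  if (length(unique(modes)) != 1L)
    stop("mode changes mid-stream are not supported")
  seqs <- vapply(bursts, function(b) b$seq, numeric(1))
  gaps <- integer(0)
  if (any(diff(seqs) != 1)) {
    if (on_gap == "error") stop("burst sequence gap detected")
    spb <- length(bursts[[1]]$samples)
    full <- seq(seqs[1], seqs[length(seqs)])
    filled <- vector("list", length(full))
    mid_code <- as.integer(2L^cfg$adc_bits / 2L)
    j <- 1L
    for (i in seq_along(full)) {
      if (j <= length(bursts) && bursts[[j]]$seq == full[i]) {
        filled[[i]] <- bursts[[j]]; j <- j + 1L
      } else {
        gaps <- c(gaps, full[i])
        filled[[i]] <- structure(
          list(seq = full[i], mode = modes[1],
               samples = rep(mid_code, spb),
               t_start = bursts[[1]]$t_start + (full[i] - seqs[1]) * spb / cfg$fs,
               partial = FALSE, n_pad = 0L),
          class = "packet_burst")
      }
    }
    bursts <- filled
  }
  codes <- depacketize(bursts)
  t0 <- bursts[[1]]$t_start
  input <- dequantize(codes, cfg, t0 = t0)
  x <- input$x
  fs <- cfg$fs
  n <- length(x)

  win_n <- round(policy$analysis_window * fs)
  period_n <- round(policy$assessment_period * fs)
  # assessment instants (sample index of the last sample the FFT may see)
  assess_at <- if (n >= win_n) seq(win_n, n, by = period_n) else integer(0)
  y <- numeric(n)
  cur_order <- 0L
  spec <- NULL
  state <- NULL
  reports <- list()
  bounds <- c(0L, assess_at, n)
  bounds <- unique(pmin(bounds, n))
  for (k in seq_len(length(bounds) - 1L)) {
    i0 <- bounds[k] + 1L
    i1 <- bounds[k + 1L]
    if (i0 > i1) next
    # segment [i0, i1] is filtered with the coefficients chosen at bounds[k]
    if (bounds[k] %in% assess_at) {
      wseg <- sampled_signal(x[seq_len(bounds[k])], fs, units = input$units,
                             channel = input$channel, t0 = t0)
      rep_k <- assess_noise(wseg, policy)
      rep_k$time <- t0 + bounds[k] / fs
      reports[[length(reports) + 1L]] <- rep_k
      new_order <- rep_k$selected_order
      if (new_order != cur_order) {
        if (new_order == 0L) {
          spec <- NULL; state <- NULL
        } else {
          spec <- design_adaptive_notch(new_order, policy$mains_freq, fs)
          state <- NULL
          if (policy$reprime == "replay") {
            nrep <- min(round(policy$reprime_window * fs), bounds[k])
            if (nrep > 0L) {
              warm <- sos_chunk(x[(bounds[k] - nrep + 1L):bounds[k]], spec$sos)
              state <- warm$state
            }
          }
        }
        cur_order <- new_order
      }
    }
    if (is.null(spec)) {
      y[i0:i1] <- x[i0:i1]
    } else {
      r <- sos_chunk(x[i0:i1], spec$sos, state)
      y[i0:i1] <- r$y
      state <- r$state
    }
  }
  list(signal = sampled_signal(y, fs, units = input$units,
                               channel = input$channel, t0 = t0),
       reports = reports, gaps = gaps)
}
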