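#' Realizable digital filters as second-order-section cascades
#'
#' All filters in the package are represented as a cascade of biquad
#' sections (one row per section: b0 b1 b2 a0 a1 a2, a0 normalized to 1),
#' the numerically robust form used by embedded and DSP toolchains.
#'
#' @param sos numeric matrix with 6 columns, one biquad per row.
#' @param fs sampling rate in Hz the design is valid for.
#' @param kind short design label ("lowpass", "highpass", "notch", ...).
#' @param params named list of design parameters (fc, f0, q, order, ...).
#' @return An object of class \code{filter_spec}.
#' @export
filter_spec <- function(sos, fs, kind = "custom", params = list()) {
  sos <- matrix(as.numeric(sos), ncol = 6L)
  if (any(abs(sos[, 4] - 1) > 1e-12)) {
    sos[, 1:3] <- sos[, 1:3] / sos[, 4]
    sos[, 5:6] <- sos[, 5:6] / sos[, 4]
    sos[, 4] <- 1
  }
  structure(list(sos = sos, fs = fs, kind = kind, params = params),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> %s, order %d (%d biquad section%s) @ fs=%g Hz\n",
              x$kind, 2L * nrow(x$sos), nrow(x$sos),
              if (nrow(x$sos) == 1L) "" else "s", x$fs))
  invisible(x)
}

#' Filter order
#' @param spec a \code{filter_spec}.
#' @return integer order (2 per biquad section).
#' @export
filter_order <- function(spec) 2L * nrow(spec$sos)

#' Poles of a filter
#' @param spec a \code{filter_spec}.
#' @return complex vector of all section poles.
#' @export
filter_poles <- function(spec) {
  unlist(lapply(seq_len(nrow(spec$sos)), function(i) {
    a <- spec$sos[i, 4:6]
    polyroot(rev(a))
  }))
}

#' Is the filter stable?
#'
#' Checks that every pole lies strictly inside the unit circle.
#' @param spec a \code{filter_spec}.
#' @return logical.
#' @export
is_stable <- function(spec) all(Mod(filter_poles(spec)) < 1)

#' Complex frequency response of a filter
#'
#' Evaluates the cascade transfer function on a vector of physical
#' frequencies.
#'
#' @param spec a \code{filter_spec}.
#' @param f frequencies in Hz (0 to fs/2).
#' @return complex vector H(f), same length as \code{f}.
#' @export
filter_response <- function(spec, f) {
  w <- 2 * pi * f / spec$fs
  z1 <- exp(-1i * w)
  z2 <- z1 * z1
  H <- rep(1 + 0i, length(f))
  for (i in seq_len(nrow(spec$sos))) {
    s <- spec$sos[i, ]
    H <- H * (s[1] + s[2] * z1 + s[3] * z2) / (s[4] + s[5] * z1 + s[6] * z2)
  }
  H
}

#' Magnitude response in dB
#' @inheritParams filter_response
#' @param floor_db values below this floor are clamped (default -400).
#' @return numeric vector 20*log10|H(f)|.
#' @export
filter_gain_db <- function(spec, f, floor_db = -400) {
  pmax(20 * log10(Mod(filter_response(spec, f))), floor_db)
}

#' Locate a -3 dB cutoff by frequency-response search
#'
#' Finds the frequency at which the magnitude response falls 3.0103 dB
#' (a factor 1/sqrt(2)) below the passband reference gain, by bisection on
#' the magnitude response. This is the measurement used to verify that
#' designed stages realize their printed band edges.
#'
#' @param spec a \code{filter_spec}.
#' @param side \code{"low"} to search the lower band edge (high-pass
#'   stages), \code{"high"} for the upper band edge (low-pass stages).
#' @param ref_freq frequency at which the passband reference gain is read;
#'   defaults to fs/4 for \code{side="low"} and fs/1e6 for
#'   \code{side="high"} — deep inside the respective passband.
#' @return the -3 dB frequency in Hz.
#' @export
find_minus3db <- function(spec, side = c("high", "low"), ref_freq = NULL) {
  side <- match.arg(side)
  nyq <- spec$fs / 2
  if (is.null(ref_freq)) {
    ref_freq <- if (side == "low") nyq / 2 else spec$fs / 1e6
  }
  ref <- Mod(filter_response(spec, ref_freq))
  target <- ref / sqrt(2)
  g <- function(f) Mod(filter_response(spec, f)) - target
  lo <- nyq * 1e-9
  hi <- nyq * (1 - 1e-9)
  # bracket: magnitude is monotone for the Butterworth stages used here
  root <- stats::uniroot(g, lower = lo, upper = hi, tol = 1e-12)
  root$root
}

# ---- filtering engines -----------------------------------------------------

# Apply one biquad (direct form I) to a chunk with carried state.
# state: list(xprev = last two inputs (oldest first), yprev = last two
# outputs (oldest first)); zero state if NULL.
biquad_chunk <- function(x, s, state = NULL) {
  if (is.null(state)) state <- list(xprev = c(0, 0), yprev = c(0, 0))
  n <- length(x)
  if (n == 0L) return(list(y = numeric(0), state = state))
  xx <- c(state$xprev, x)
  v <- stats::filter(xx, s[1:3], method = "convolution", sides = 1)
  v <- as.numeric(v)[3:(n + 2L)]
  # recursive part: y[i] = v[i] - a1*y[i-1] - a2*y[i-2]
  y <- as.numeric(stats::filter(v, -s[5:6], method = "recursive",
                                init = rev(state$yprev)))
  list(y = y,
       state = list(xprev = c(state$xprev, x)[(n + 1L):(n + 2L)],
                    yprev = c(state$yprev, y)[(n + 1L):(n + 2L)]))
}

# Apply a full sos cascade to a chunk with carried per-section state.
# state: list of per-section states (or NULL for zero initial conditions).
sos_chunk <- function(x, sos, state = NULL) {
  ns <- nrow(sos)
  if (is.null(state)) state <- vector("list", ns)
  y <- x
  for (i in seq_len(ns)) {
    r <- biquad_chunk(y, sos[i, ], state[[i]])
    y <- r$y
    state[[i]] <- r$state
  }
  list(y = y, state = state)
}

#' Apply a filter to a signal (causal, zero initial state)
#'
#' @param spec a \code{filter_spec}.
#' @param sig a \code{sampled_signal} (its fs must equal the design fs) or a
#'   plain numeric vector.
#' @return filtered signal of the same type as the input.
#' @export
apply_filter <- function(spec, sig) {
  if (inherits(sig, "sampled_signal")) {
    if (abs(sig$fs - spec$fs) > 1e-9)
      stop(sprintf("signal fs (%g) does not match filter design fs (%g)",
                   sig$fs, spec$fs))
    replace_samples(sig, sos_chunk(sig$x, spec$sos)$y)
  } else {
    sos_chunk(as.numeric(sig), spec$sos)$y
  }
}

#' Streaming filter state handle
#'
#' Creates a stateful filtering closure: successive calls filter successive
#' chunks with exact state carry-over, so that chunk-wise output is
#' bit-identical to filtering the concatenated input in one pass.
#'
#' @param spec a \code{filter_spec}.
#' @return a function \code{f(chunk)} returning the filtered chunk.
#' @export
streaming_filter <- function(spec) {
  state <- NULL
  sos <- spec$sos
  function(chunk) {
    r <- sos_chunk(chunk, sos, state)
    state <<- r$state
    r$y
  }
}
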