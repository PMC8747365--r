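#' Uniformly sampled single-channel signal
#'
#' The basic container used throughout the package: an amplitude vector
#' sampled at a fixed rate, tagged with physical units and a channel kind
#' (\code{"ECG"} or \code{"EMG"}).
#'
#' @param x numeric vector of sample amplitudes.
#' @param fs sampling rate in Hz (positive scalar).
#' @param units amplitude units, default \code{"mV"}.
#' @param channel channel kind, \code{"ECG"} or \code{"EMG"}.
#' @param t0 time of the first sample in seconds.
#' @param meta optional named list of provenance metadata (seed, generator
#'   parameters); carried along and written to the CSV sidecar header.
#' @return An object of class \code{sampled_signal}.
#' @export
sampled_signal <- function(x, fs, units = "mV", channel = c("ECG", "EMG"),
                           t0 = 0, meta = list()) {
  channel <- match.arg(channel)
  stopifnot(is.numeric(x), is.numeric(fs), length(fs) == 1L, fs > 0)
  if (anyNA(x)) stop("signal contains NA values")
  structure(list(x = as.numeric(x), fs = as.numeric(fs), units = units,
                 channel = channel, t0 = as.numeric(t0), meta = meta),
            class = "sampled_signal")
}

#' Sample times of a signal
#' @param sig a \code{sampled_signal}.
#' @return numeric vector of sample times in seconds.
#' @export
signal_times <- function(sig) {
  stopifnot(inherits(sig, "sampled_signal"))
  sig$t0 + (seq_along(sig$x) - 1L) / sig$fs
}

#' Duration of a signal in seconds
#' @param sig a \code{sampled_signal}.
#' @export
signal_duration <- function(sig) length(sig$x) / sig$fs

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %s channel, %d samples @ %g Hz (%.3f s), units %s\n",
              x$channel, length(x$x), x$fs, signal_duration(x), x$units))
  invisible(x)
}

#' @export
plot.sampled_signal <- function(x, ...) {
  plot(signal_times(x), x$x, type = "l",
       xlab = "time [s]", ylab = sprintf("amplitude [%s]", x$units),
       main = sprintf("%s signal", x$channel), ...)
  invisible(x)
}

#' @export
length.sampled_signal <- function(x) length(x$x)

# internal: replace the amplitude vector, keeping metadata
replace_samples <- function(sig, x, units = sig$units) {
  sampled_signal(x, fs = sig$fs, units = units, channel = sig$channel,
                 t0 = sig$t0, meta = sig$meta)
}
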