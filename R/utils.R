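# Internal numerical helpers shared across modules.

# Evaluate expr with a local RNG state: seeds the generator, restores the
# caller's .Random.seed afterwards. All package randomness flows through
# explicit seed arguments via this helper; no hidden global state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

# Centered moving average with window of n samples (n >= 1). Edges use the
# partial window (running mean over available samples).
moving_average <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n == 1L) return(x)
  cs <- cumsum(c(0, x))
  half <- n %/% 2L
  i <- seq_along(x)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + (n - 1L - half), length(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Welch power spectral density estimate
#'
#' Segment-averaged periodogram with a Hann window and 50\% overlap; the
#' standard noise-robust PSD estimator used by the noise-assessment and
#' frequency-domain HRV routines.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param nperseg segment length in samples (default \code{min(length(x), 256)}).
#' @param overlap fractional overlap between segments (default 0.5).
#' @param demean subtract each segment's mean before windowing (default TRUE).
#' @return data.frame with columns \code{freq} (Hz) and \code{psd}
#'   (power per Hz, one-sided).
#' @export
welch_psd <- function(x, fs, nperseg = min(length(x), 256L), overlap = 0.5,
                      demean = TRUE) {
  x <- as.numeric(x)
  n <- length(x)
  nperseg <- min(as.integer(nperseg), n)
  stopifnot(nperseg >= 8L, overlap >= 0, overlap < 1)
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))  # Hann
  u <- sum(w^2)
  nfreq <- nperseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    if (demean) seg <- seg - mean(seg)
    X <- stats::fft(seg * w)[seq_len(nfreq)]
    acc <- acc + Mod(X)^2
  }
  psd <- acc / (length(starts) * u * fs)
  # one-sided: double everything except DC (and Nyquist when nperseg even)
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (nperseg %% 2L == 0L) dbl[nfreq] <- 1
  data.frame(freq = (seq_len(nfreq) - 1L) * fs / nperseg, psd = psd * dbl)
}

# Integrate a PSD over [f_lo, f_hi] by the trapezoidal rule.
band_power <- function(psd_df, f_lo, f_hi) {
  f <- psd_df$freq
  p <- psd_df$psd
  keep <- f >= f_lo & f <= f_hi
  if (sum(keep) < 2L) return(sum(p[keep]) * if (length(f) > 1) diff(f[1:2]) else 0)
  fk <- f[keep]
  pk <- p[keep]
  sum(diff(fk) * (pk[-1] + pk[-length(pk)]) / 2)
}
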