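# Shared fixture builders. Everything is generated in code; no data files.

# clean synthetic ECG with its ground-truth schedule
make_ecg <- function(duration = 60, hr = 60, fs = 1000, hrv = NULL, seed = 1L) {
  sch <- beat_schedule(duration = duration, mean_hr = hr, hrv = hrv, seed = seed)
  c(generate_ecg(sch, fs = fs), list(fs = fs))
}

# device chain: AFE -> quantize -> packetize
through_device <- function(sig, cfg) {
  packetize(quantize(apply_afe(sig, cfg), cfg), cfg$fs, mode = sig$channel)
}

# literal 2^n enumeration oracle for the Wilcoxon signed-rank two-sided p
wilcoxon_brute_force <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- as.vector(signs %*% r)
  obs <- sum(r[d > 0])
  p_le <- mean(W <= obs + 1e-9)
  p_ge <- mean(W >= obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
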