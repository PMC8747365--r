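test_that("biquad designs realize their printed -3 dB cutoffs", {
  cases <- list(list(f = design_biquad_lowpass(41, 10000), side = "high",
                     fc = 41, tol = 0.5),
                list(f = design_biquad_highpass(0.34, 10000), side = "low",
                     fc = 0.34, tol = 0.01),
                list(f = design_biquad_highpass(40.17, 10000), side = "low",
                     fc = 40.17, tol = 0.5),
                list(f = design_biquad_lowpass(727, 10000), side = "high",
                     fc = 727, tol = 5))
  for (cs in cases) {
    expect_true(is_stable(cs$f))
    got <- find_minus3db(cs$f, cs$side)
    expect_lt(abs(got - cs$fc), cs$tol)
    # tight invariant: realized cutoff within 1% of requested
    expect_lt(abs(got - cs$fc), 0.01 * cs$fc)
    # -3 dB +/- 0.1 dB at fc relative to passband
    ref <- if (cs$side == "high") 1e-3 else 4000
    rel_db <- filter_gain_db(cs$f, cs$fc) - filter_gain_db(cs$f, ref)
    expect_lt(abs(rel_db + 20 * log10(sqrt(2))), 0.1)
  }
  expect_error(design_biquad_lowpass(6000, 10000), "fs/2")
})

test_that("biquad designs agree with an independent Butterworth designer", {
  bt <- signal::butter(2, 41 / 5000, type = "low")
  mine <- design_biquad_lowpass(41, 10000)
  expect_equal(as.numeric(mine$sos[1, 1:3]), as.numeric(bt$b), tolerance = 1e-10)
  expect_equal(as.numeric(mine$sos[1, 4:6]), as.numeric(bt$a), tolerance = 1e-10)
  bt2 <- signal::butter(2, 0.34 / 5000, type = "high")
  mine2 <- design_biquad_highpass(0.34, 10000)
  expect_equal(as.numeric(mine2$sos[1, 1:3]), as.numeric(bt2$b), tolerance = 1e-8)
  expect_equal(as.numeric(mine2$sos[1, 4:6]), as.numeric(bt2$a), tolerance = 1e-8)
})

test_that("monotone magnitude (Butterworth) response of the band-limiting stages", {
  f <- seq(0.01, 4999, length.out = 2000)
  lp <- Mod(filter_response(design_biquad_lowpass(41, 10000), f))
  expect_true(all(diff(lp) < 1e-12))
  hp <- Mod(filter_response(design_biquad_highpass(40.17, 10000), f))
  expect_true(all(diff(hp) > -1e-12))
})

test_that("twin-T-equivalent notch rejects the line and passes everything else", {
  nt <- design_twin_t_notch(60, 10000, q = 5)
  expect_true(is_stable(nt))
  grid <- seq(59.5, 60.5, by = 0.001)
  expect_true(all(filter_gain_db(nt, 60) <= -30))
  expect_lt(max(filter_gain_db(nt, grid[abs(grid - 60) < 0.05])), -30)
  expect_lt(abs(Mod(filter_response(nt, 1e-9)) - 1), 0.01)  # DC gain 1
  expect_lt(abs(filter_gain_db(nt, 180)), 1)                # 3rd harmonic < 1 dB
  # time-domain oracle: pure 60 Hz tone attenuated >= 30 dB after transient
  fs <- 10000
  tone <- sin(2 * pi * 60 * (0:(2 * fs - 1)) / fs)
  y <- apply_filter(nt, tone)
  rms_in <- sqrt(mean(tone[(fs + 1):(2 * fs)]^2))
  rms_out <- sqrt(mean(y[(fs + 1):(2 * fs)]^2))
  expect_lt(20 * log10(rms_out / rms_in), -30)
})

test_that("the AFE cascade amplifies mid-band by the configured gain", {
  cfg <- afe_config("ECG", fs = 1000)
  fs <- 1000
  tone <- sampled_signal(sin(2 * pi * 4 * (0:(20 * fs - 1)) / fs), fs)
  out <- apply_afe(tone, cfg)
  amp <- max(out$x[(10 * fs):(20 * fs)])   # steady state
  expect_equal(amp, 1100, tolerance = 0.05 * 1100)
  # mid-band (geometric mean of cutoffs) frequency-response gain within 5%
  expect_equal(Mod(afe_response(cfg, sqrt(0.34 * 41))), 1100,
               tolerance = 0.05 * 1100)
  # DC blocked by the high-pass (after the slow 0.34 Hz transient decays)
  dc <- apply_afe(sampled_signal(rep(1, 20 * fs), fs), cfg)
  expect_lt(max(abs(dc$x[(19 * fs):(20 * fs)])), 1e-2)
})

test_that("AFE is linear and its response is the product of stage responses", {
  cfg <- afe_config("ECG", fs = 1000)
  set.seed(8)
  x <- sampled_signal(rnorm(4000), 1000)
  y1 <- apply_afe(x, cfg)
  y3 <- apply_afe(sampled_signal(3 * x$x, 1000), cfg)
  expect_equal(y3$x, 3 * y1$x, tolerance = 1e-9)
  f <- seq(0.1, 450, by = 0.37)
  prod_resp <- filter_response(design_biquad_highpass(0.34, 1000), f) *
    filter_response(design_biquad_lowpass(41, 1000), f) * 1100 *
    filter_response(design_twin_t_notch(60, 1000, 5), f)
  expect_lt(max(abs(20 * log10(Mod(afe_response(cfg, f))) -
                    20 * log10(Mod(prod_resp)))), 0.1)
  # off-notch attenuation matches the per-stage product; at the notch center
  # the chain response is a true zero and the steady-state residual vanishes
  tone50 <- sampled_signal(sin(2 * pi * 50 * (0:19999) / 1000), 1000)
  amp50 <- max(abs(apply_afe(tone50, cfg)$x[15000:20000]))
  expect_equal(amp50, Mod(afe_response(cfg, 50)), tolerance = 0.05 * amp50)
  tone60 <- sampled_signal(sin(2 * pi * 60 * (0:19999) / 1000), 1000)
  expect_lt(max(abs(apply_afe(tone60, cfg)$x[15000:20000])), 1e-6)
  expect_lt(Mod(afe_response(cfg, 60)), 1e-9)
  # channel mismatch is rejected
  emg <- sampled_signal(rnorm(1000), 1000, channel = "EMG")
  expect_error(apply_afe(emg, cfg), "channel")
})

test_that("mid-rise quantization has half-LSB error, defined edges and clipping", {
  cfg <- afe_config("ECG", fs = 1000)
  expect_equal(2^cfg$adc_bits, 256)
  lsb <- (cfg$adc_full_scale[2] - cfg$adc_full_scale[1]) / 256
  # dense in-range grid: round-trip error <= LSB/2 everywhere
  xs <- seq(cfg$adc_full_scale[1], cfg$adc_full_scale[2], length.out = 20001)
  sig <- sampled_signal(xs, 1000)
  q <- quantize(sig, cfg)
  expect_equal(attr(q, "lsb"), lsb)
  dq <- dequantize(q, cfg)
  expect_lte(max(abs(dq$x - xs)), lsb / 2 + 1e-12)
  # exact full-scale top maps to the top code; clipping is counted
  edge <- quantize(sampled_signal(c(cfg$adc_full_scale[2],
                                    cfg$adc_full_scale[1], 1e6), 1000), cfg)
  expect_identical(as.integer(edge)[1:2], c(255L, 0L))
  expect_identical(as.integer(edge)[3], 255L)
  expect_identical(attr(edge, "n_clipped"), 1L)
})

test_that("packetization is lossless, order-preserving, and 240 samples per burst", {
  b <- packetize(0:2399, 10000, "ECG")
  expect_length(b, 10)
  expect_true(all(vapply(b, function(x) length(x$samples), integer(1)) == 240L))
  expect_identical(depacketize(b), 0:2399)
  expect_identical(packetize(integer(0), 10000, "ECG"), list())
  # trailing partial: padded and flagged
  b2 <- packetize(0:249, 10000, "ECG")
  expect_length(b2, 2)
  expect_true(b2[[2]]$partial)
  expect_identical(b2[[2]]$n_pad, 230L)
  expect_identical(depacketize(b2), 0:249)
  expect_error(packetize(1:100, 999, "ECG"), "integral")
  # property: round trip over random lengths
  for (n in c(1, 239, 240, 241, 1000, 4801)) {
    codes <- as.integer(seq_len(n) %% 256)
    expect_identical(depacketize(packetize(codes, 10000, "EMG")), codes)
  }
})

test_that("battery lifetime is capacity over average draw", {
  expect_equal(estimate_lifetime(235, 4), 58.75)
  expect_gt(estimate_lifetime(235, 4), 58)
  expect_equal(estimate_lifetime(1, 1), 1)
  expect_equal(estimate_lifetime(100, 4), 25)
  expect_error(estimate_lifetime(0, 4), "positive")
  expect_error(estimate_lifetime(100, -1), "positive")
})
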