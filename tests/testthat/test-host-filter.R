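test_that("noise assessment maps PLI level to notch order monotonically", {
  pol <- adaptive_policy()
  fx <- make_ecg(duration = 10, hr = 70, fs = 1000)
  # clean in-band ECG: no PLI energy -> bypass
  r0 <- assess_noise(fx$signal, pol)
  expect_lt(r0$pli_ratio, 0.01)
  expect_identical(r0$selected_order, 0L)
  # pure tone: ratio ~ 1 -> maximum order 12
  tone <- sampled_signal(sin(2 * pi * 60 * (0:9999) / 1000), 1000)
  r1 <- assess_noise(tone, pol)
  expect_gt(r1$pli_ratio, 0.95)
  expect_identical(r1$selected_order, 12L)
  # monotone in amplitude
  amps <- c(0.02, 0.05, 0.1, 0.3, 0.7, 2, 8)
  res <- lapply(amps, function(a)
    assess_noise(add_interference(fx$signal, interference_spec(60, a), seed = 2),
                 pol))
  ratios <- vapply(res, function(r) r$pli_ratio, numeric(1))
  orders <- vapply(res, function(r) r$selected_order, integer(1))
  expect_true(all(diff(ratios) > 0))
  expect_true(all(diff(orders) >= 0))
  expect_true(all(orders %% 2 == 0 & orders <= 12))
  # short window rejected with the required length in the message
  short <- sampled_signal(rnorm(100), 1000)
  expect_error(assess_noise(short, pol), "needs >= 1000")
})

test_that("order 0 iff ratio below the lowest threshold", {
  pol <- adaptive_policy()
  th <- pol$ratio_thresholds
  expect_identical(wearbiosig:::pli_order(th[1] / 2, th), 0L)
  expect_identical(wearbiosig:::pli_order(th[1], th), 2L)
  expect_identical(wearbiosig:::pli_order(th[6] + 1e-9, th), 12L)
  expect_identical(wearbiosig:::pli_order(0.999, th), 12L)
})

test_that("adaptive notch cascade: stability, passband, and depth by order", {
  for (mains in c(50, 60)) {
    resid <- numeric(0)
    for (ord in seq(2, 12, by = 2)) {
      nt <- design_adaptive_notch(ord, mains, 1000)
      expect_true(is_stable(nt))
      expect_identical(filter_order(nt), as.integer(ord))
      # passband probe at 10 Hz within 1 dB of unity at every order
      expect_lt(abs(filter_gain_db(nt, 10)), 1)
      # mean attenuation in the mains band strictly deepens with order
      band <- seq(mains - 0.5, mains + 0.5, by = 0.01)
      resid <- c(resid, mean(Mod(filter_response(nt, band))))
    }
    expect_true(all(diff(resid) < 0))
  }
  expect_error(design_adaptive_notch(3, 60, 1000), "even")
  expect_error(design_adaptive_notch(0, 60, 1000), "even")
})

test_that("order-12 notch removes a mains tone to below -60 dB", {
  fs <- 1000
  tone <- sin(2 * pi * 60 * (0:(10 * fs - 1)) / fs)
  y12 <- apply_filter(design_adaptive_notch(12, 60, fs), tone)
  ss <- (5 * fs):(10 * fs)
  rms_in <- sqrt(mean(tone[ss]^2))
  expect_lt(20 * log10(sqrt(mean(y12[ss]^2)) / rms_in), -60)
  # deeper cascade leaves a strictly smaller residual on a slightly detuned
  # tone (at the exact center both residuals sit at the numerical floor)
  det <- sin(2 * pi * 60.3 * (0:(10 * fs - 1)) / fs)
  r12 <- sqrt(mean(apply_filter(design_adaptive_notch(12, 60, fs), det)[ss]^2))
  r2 <- sqrt(mean(apply_filter(design_adaptive_notch(2, 60, fs), det)[ss]^2))
  expect_lt(r12, r2)
})

test_that("streaming filtering equals batch filtering exactly", {
  nt <- design_adaptive_notch(6, 60, 1000)
  set.seed(5)
  x <- rnorm(10000)
  batch <- apply_filter(nt, x)
  sf <- streaming_filter(nt)
  cuts <- c(0, sort(sample(1:9999, 7)), 10000)
  streamed <- unlist(lapply(seq_len(length(cuts) - 1L), function(i)
    sf(x[(cuts[i] + 1):cuts[i + 1]])))
  expect_identical(streamed, batch)
})

test_that("clean streams pass through with the filter never engaged", {
  fx <- make_ecg(duration = 90, hr = 70, fs = 1000)
  cfg <- afe_config("ECG", fs = 1000)
  pol <- adaptive_policy(assessment_period = 10)
  bursts <- through_device(fx$signal, cfg)
  out <- stream_filter(bursts, pol, cfg)
  orders <- vapply(out$reports, function(r) r$selected_order, integer(1))
  expect_true(all(orders == 0L))
  # passthrough: output equals the dequantized input exactly
  expect_identical(out$signal$x, dequantize(depacketize(bursts), cfg)$x)
  # determinism: same bursts twice -> bit-identical
  out2 <- stream_filter(bursts, pol, cfg)
  expect_identical(out$signal$x, out2$signal$x)
})

test_that("strong mains contamination engages order 12 and flattens the 60 Hz peak", {
  fx <- make_ecg(duration = 90, hr = 70, fs = 1000)
  cfg <- afe_config("ECG", fs = 1000, notch_enabled = FALSE)
  pol <- adaptive_policy(assessment_period = 10)
  noisy <- add_interference(fx$signal,
                            interference_spec(60, 2, broadband_noise_sd = 0.02),
                            seed = 5)
  out <- stream_filter(through_device(noisy, cfg), pol, cfg)
  orders <- vapply(out$reports, function(r) r$selected_order, integer(1))
  expect_identical(orders[1], 12L)
  # post-filter spectrum: no 60 Hz peak exceeding the neighboring median by > 3 dB
  ps <- welch_psd(out$signal$x[20000:90000], 1000, nperseg = 4096)
  pk <- max(ps$psd[abs(ps$freq - 60) < 1])
  nbhd <- median(ps$psd[abs(ps$freq - 60) >= 2 & abs(ps$freq - 60) <= 10])
  expect_lt(10 * log10(pk / nbhd), 3)
})

test_that("burst streams reject mode changes and honor the gap policy", {
  cfg <- afe_config("ECG", fs = 1000)
  sig <- sampled_signal(rnorm(24 * 100), 1000)
  bursts <- through_device(sig, cfg)
  mixed <- bursts
  mixed[[3]]$mode <- "EMG"
  pol <- adaptive_policy()
  expect_error(stream_filter(mixed, pol, cfg), "mode")
  gappy <- bursts[-3]
  expect_error(stream_filter(gappy, pol, cfg), "gap")
  filled <- stream_filter(gappy, pol, cfg, on_gap = "zero_fill")
  expect_identical(filled$gaps, 2L)
  expect_length(filled$signal$x, length(bursts) * 24L)
})
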