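test_that("scheduled beats produce R deflections at the scheduled times", {
  fx <- make_ecg(duration = 10, hr = 60, fs = 1000)
  expect_identical(fx$schedule$beat_times, seq(1, 10, by = 1))
  # largest local maxima within +/- 2 ms of each beat time
  x <- fx$signal$x
  for (bt in fx$schedule$beat_times) {
    i <- round(bt * fx$fs) + 1L
    w <- max(1, i - 100):min(length(x), i + 100)
    expect_lte(abs((w[which.max(x[w])] - 1) / fx$fs - bt) * 1000, 2)
  }
})

test_that("a single-beat schedule yields exactly one R-wave", {
  sch <- beat_schedule(beat_times = 2)
  sig <- generate_ecg(sch, fs = 1000, duration = 4)$signal
  x <- sig$x
  expect_equal(which.max(x), 2001, tolerance = 0.002)
  # flat outside the template support (|t - 2| > 0.5 s)
  tt <- signal_times(sig)
  expect_true(all(abs(x[abs(tt - 2) > 0.5]) < 1e-6))
})

test_that("sinusoidal HRV modulation is recoverable from the rendered signal", {
  fx <- make_ecg(duration = 120, hr = 60, fs = 1000,
                 hrv = list(type = "sinusoidal", freq = 0.1, depth_ms = 50))
  # oracle: argmax per +/-200 ms window around each scheduled beat
  x <- fx$signal$x
  det <- vapply(fx$schedule$beat_times, function(bt) {
    i <- round(bt * fx$fs) + 1L
    w <- max(1, i - 200):min(length(x), i + 200)
    (w[which.max(x[w])] - 1) / fx$fs
  }, numeric(1))
  rr_det <- diff(det) * 1000
  rr_true <- diff(fx$schedule$beat_times) * 1000
  expect_lt(sqrt(mean((rr_det - rr_true)^2)), 5)
})

test_that("beat schedules enforce physiological invariants", {
  expect_error(beat_schedule(beat_times = c(1, 1.1)), "refractory")
  expect_error(beat_schedule(beat_times = c(2, 1)), "strictly increasing")
  sch <- beat_schedule(duration = 300, mean_hr = 75)
  expect_equal(sch$mean_hr, 75, tolerance = 1e-6)
  # jittered schedule keeps its mean rate within the stated jitter
  schj <- beat_schedule(duration = 600, mean_hr = 80,
                        hrv = list(type = "jitter", sd_ms = 20), seed = 3)
  expect_equal(schj$mean_hr, 80, tolerance = 1)
})

test_that("overlapping beats are rejected when the template cannot shrink", {
  sch <- beat_schedule(duration = 10, mean_hr = 150)
  m <- ecg_morphology(scale_with_rr = FALSE)
  expect_error(generate_ecg(sch, fs = 1000, morphology = m), "overlap")
  expect_silent(generate_ecg(sch, fs = 1000))  # rate-adaptive template is fine
})

test_that("EMG generator output tracks envelope x carrier_sd and is seeded", {
  zero <- generate_emg(emg_activation(0, 0, duration = 2), fs = 2000, seed = 1)
  expect_true(all(zero$signal$x == 0))

  pr <- emg_activation(0, 1, duration = 10, carrier_sd = 0.1)
  g <- generate_emg(pr, fs = 10000, seed = 42)
  w <- windowed_rms(g$signal, window = 0.2)
  expect_gte(mean(abs(w$rms - 0.1) < 0.01), 0.95)

  # deterministic under fixed seed; different under another
  g2 <- generate_emg(pr, fs = 10000, seed = 42)
  expect_identical(g$signal$x, g2$signal$x)
  g3 <- generate_emg(pr, fs = 10000, seed = 43)
  expect_false(identical(g$signal$x, g3$signal$x))

  # step envelope: RMS after the step exceeds RMS before in every paired window
  st <- emg_activation(c(0, 5), c(0.2, 1), duration = 10, carrier_sd = 0.1)
  gs <- generate_emg(st, fs = 2000, seed = 7)
  ws <- windowed_rms(gs$signal, window = 0.2)
  pre <- ws$rms[ws$t_mid < 5]
  post <- ws$rms[ws$t_mid > 5]
  n <- min(length(pre), length(post))
  expect_true(all(post[seq_len(n)] > pre[seq_len(n)]))

  expect_error(generate_emg(emg_activation(0, 1, duration = 1,
                                           carrier_band = c(20, 600)),
                            fs = 1000), "Nyquist")
})

test_that("interference is additive, deterministic, and spectrally correct", {
  z <- sampled_signal(numeric(2000), 1000)
  # zero amplitudes: identity
  same <- add_interference(z, interference_spec(60, 0), seed = 1)
  expect_identical(same$x, z$x)
  # pure 60 Hz on zero signal equals the closed-form sinusoid exactly
  tone <- add_interference(z, interference_spec(60, 0.25), seed = 1)
  expect_identical(tone$x, 0.25 * sin(2 * pi * 60 * signal_times(z)))
  # mains peak dominates the PSD of the injected noise
  fx <- make_ecg(duration = 20, fs = 1000)
  noisy <- add_interference(fx$signal, interference_spec(60, 0.5), seed = 2)
  ps <- welch_psd(noisy$x - fx$signal$x, 1000, nperseg = 2048)
  expect_equal(ps$freq[which.max(ps$psd)], 60, tolerance = 1)
  # and exceeds the ECG's own in-band energy density at 60 Hz
  ps_ecg <- welch_psd(fx$signal$x, 1000, nperseg = 2048)
  expect_gt(max(welch_psd(noisy$x, 1000, nperseg = 2048)$psd[abs(ps$freq - 60) < 1]),
            max(ps_ecg$psd[abs(ps_ecg$freq - 60) < 1]) * 10)
  expect_error(interference_spec(55), "50 or 60")
  expect_silent(interference_spec(55, strict = FALSE))
})

test_that("injected interference variance adds up over a long record", {
  z <- sampled_signal(numeric(90000), 1000)
  spec <- interference_spec(60, c(0.5, 0.2),
                           baseline_wander = list(amplitude = 0.3, freq = 0.25),
                           broadband_noise_sd = 0.1)
  ns <- add_interference(z, spec, seed = 4)
  injected <- 0.5^2 / 2 + 0.2^2 / 2 + 0.3^2 / 2 + 0.1^2
  expect_equal(var(ns$x), injected, tolerance = 0.02 * injected)
})

test_that("generators return the exact ground truth they used", {
  sch <- beat_schedule(duration = 15, mean_hr = 72)
  out <- generate_ecg(sch, fs = 500)
  expect_identical(out$schedule, sch)
  pr <- emg_activation(c(0, 3), c(0.1, 0.8), duration = 6)
  expect_identical(generate_emg(pr, fs = 2000, seed = 5)$profile, pr)
})
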