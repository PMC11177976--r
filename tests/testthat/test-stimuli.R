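test_that("raised-cosine ramps have the right shape and preserve duration", {
  fs <- 1e3
  w <- waveform(rep(1, 301), fs)
  expect_identical(apply_ramp(w, 0)$samples, w$samples)
  r <- apply_ramp(w, 0.101)  # 101-sample ramp (odd): exact midpoint sample
  expect_equal(length(r$samples), length(w$samples))
  expect_equal(r$samples[1], 0)
  expect_equal(r$samples[length(r$samples)], 0)
  expect_equal(r$samples[51], 0.5)           # temporal midpoint of the ramp
  expect_equal(r$samples[150], 1)            # interior untouched
  expect_error(apply_ramp(w, 0.2), "half the waveform")
})

test_that("level calibration follows the dB SPL convention", {
  fs <- 1e4
  t <- (0:9999) / fs
  sine <- waveform(sqrt(2) * 0.02 * sin(2 * pi * 100 * t), fs)
  expect_equal(measure_level(sine), 60, tolerance = 1e-6)  # RMS 0.02 Pa
  w2 <- set_level(sine, 80)
  expect_equal(measure_level(w2), 80, tolerance = 1e-9)
  expect_equal(w2$samples, 10 * set_level(sine, 60)$samples, tolerance = 1e-9)
  expect_error(set_level(waveform(numeric(100), fs), 60), "all-zero")
  # round-trip accuracy < 0.01 dB on arbitrary signals
  set.seed(1)
  w3 <- set_level(waveform(rnorm(5000), fs), 47.3)
  expect_lt(abs(measure_level(w3) - 47.3), 0.01)
})

test_that("tones are calibrated, ramped and Nyquist-guarded", {
  w <- make_tone(1000, dur = 0.2, level = 70, fs = 1e5)
  expect_equal(length(w$samples), 20000)
  # 10-ms ramps shave a little RMS; compare against the unramped target
  expect_equal(sqrt(mean(set_level(w, 70)$samples^2)), 20e-6 * 10^3.5,
               tolerance = 1e-6)
  expect_equal(w$samples[1], 0)
  expect_error(make_tone(60000, fs = 1e5), "Nyquist")
})

test_that("SAM noise hits the overall level implied by its spectrum level", {
  w <- make_sam_noise(fm = 50, mod_depth = 1, dur = 0.5, fs = 5e4, seed = 3)
  expect_equal(measure_level(w), 30 + 10 * log10(9900), tolerance = 1e-6)
  wu <- make_sam_noise(fm = 50, mod_depth = 0, dur = 0.5, fs = 5e4, seed = 3)
  expect_equal(measure_level(wu), measure_level(w), tolerance = 1e-6)
  expect_error(make_sam_noise(50, mod_depth = 1.5), "mod_depth")
  # band limiting: negligible power outside the requested band
  sp <- abs(fft(w$samples))^2
  f <- (seq_along(sp) - 1) / length(sp) * w$fs
  inband <- f >= 90 & f <= 10100
  expect_gt(sum(sp[inband]) / sum(sp[f <= w$fs / 2]), 0.99)
})

test_that("click trains are rarefaction pulses at peak-equivalent level", {
  w <- make_click_train(200, level = 130, dur = 1, fs = 1e5)
  expect_lte(max(w$samples), 0)
  expect_equal(min(w$samples), -sqrt(2) * 20e-6 * 10^6.5, tolerance = 1e-9)
  # 200 clicks of 10 samples each
  expect_equal(sum(w$samples < 0), 200 * 10)
  expect_error(make_click_train(2000, click_dur = 1e-3), "overlap")
})

test_that("chirp construction solves the velocity-fundamental relation", {
  spec <- chirp_train_spec()
  # printed velocity set maps to F0 = {25, 50, 100, 200, 400, 600} Hz approx
  f0 <- vapply(c(0.40, 0.80, 1.59, 3.16, 6.24, 9.24), chirp_f0, numeric(1))
  expect_equal(f0[3:6], c(100, 200, 400, 600), tolerance = 1e-9)
  expect_equal(f0[1:2], c(25, 50), tolerance = 0.01)
  for (v in spec$velocities) {
    f0v <- chirp_f0(v)
    expect_equal((16000 - f0v) * f0v, abs(v) * 1e6, tolerance = 1e-6)
    w <- make_chirp(v, spec, fs = 1e5)
    expect_lt(abs(wave_duration(w) - 1 / f0v), 1 / 1e5 + 1e-12)  # one sample
  }
  # the +/-6.24 kHz/ms chirp lasts 2.5 ms and is the level reference
  expect_equal(wave_duration(make_chirp(6.24, spec, 1e5)), 2.5e-3)
  expect_equal(measure_level(make_chirp(6.24, spec, 1e5)), 65, tolerance = 1e-6)
  # energy-normalizing level law: 65 - 10*log10(T/T_ref)
  expect_equal(measure_level(make_chirp(1.59, spec, 1e5)),
               65 - 10 * log10(4), tolerance = 1e-6)
  expect_error(make_chirp(70, spec, 1e5), "solution")
})

test_that("chirp energies are equal across all twelve velocities", {
  spec <- chirp_train_spec()
  en <- vapply(spec$velocities, function(v) {
    w <- make_chirp(v, spec, fs = 1e5)
    sum(w$samples^2) / w$fs
  }, numeric(1))
  expect_lt((max(en) - min(en)) / mean(en), 0.01)
})

test_that("chirp sequences have exact condition counts, bounded gaps, and a
           consistent event log", {
  spec <- chirp_train_spec(n_reps = 5, seed = 42)
  out <- make_chirp_sequence(spec, fs = 5e4)
  ev <- out$events
  expect_equal(nrow(ev), 12 * 5)
  expect_equal(unname(table(ev$velocity_khz_per_ms)), rep(5L, 12),
               ignore_attr = TRUE)
  expect_true(all(diff(ev$onset_s) > 0))
  gaps <- c(ev$onset_s[1], ev$onset_s[-1] - ev$offset_s[-nrow(ev)])
  expect_true(all(gaps >= 0.04 - 1e-6 & gaps <= 0.06 + 1e-6))
  # events tile the waveform: each chirp segment has energy, gaps are silent
  i_gap <- round((ev$offset_s[1] + 1e-4) * 5e4):round((ev$onset_s[2] - 1e-4) * 5e4)
  expect_equal(max(abs(out$waveform$samples[i_gap])), 0)
  # determinism
  out2 <- make_chirp_sequence(spec, fs = 5e4)
  expect_identical(out$waveform$samples, out2$waveform$samples)
  expect_identical(out$events, out2$events)
  # per-event duration matches the velocity's construction
  durs <- ev$offset_s - ev$onset_s
  expect_equal(durs, 1 / vapply(ev$velocity_khz_per_ms, chirp_f0, numeric(1)),
               tolerance = 1e-3)
})
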