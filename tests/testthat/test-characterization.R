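test_that("mean_rate integrates the rate function over a window", {
  fs <- 1e4
  lam <- constant_rate(100, dur = 1, fs = fs)
  expect_equal(mean_rate(lam), 100, tolerance = 1e-9)
  expect_equal(mean_rate(constant_rate(0, dur = 1, fs = fs)), 0)
  # unit-area pulse inside a 0.5-s window -> 2 spikes/s
  pulse <- rate_function(c(numeric(1000), rep(fs / 100, 100),
                           numeric(3900)), fs)
  expect_equal(mean_rate(pulse, 0, 0.5), 2, tolerance = 1e-6)
  expect_error(mean_rate(lam, 0.5, 0.2), "t0 < t1")
})

test_that("threshold-crossing counter honors the refractory lockout", {
  fs <- 1e4
  lam <- numeric(fs)  # 1 s
  # peaks at 100 ms and 100.5 ms (0.5 ms apart -> one count), plus 300 ms
  lam[c(1000:1002, 1005:1007, 3000:3002)] <- 200
  r <- rate_function(lam, fs)
  expect_equal(count_threshold_crossings(r, 110, 1e-3), 2L)
  expect_equal(count_threshold_crossings(r, 110, 1e-5), 3L)
  expect_equal(count_threshold_crossings(constant_rate(0, fs = fs), 110,
                                         1e-3), 0L)
  expect_error(count_threshold_crossings(r, 110, 0), "refractory")
})

test_that("RVF scoring integrates a 15-ms window at the response peak", {
  fs <- 1e4
  lam <- numeric(2 * fs)
  # unit-area pulse 5 ms after the event onset at 1 s
  lam[(1.005 * fs):(1.005 * fs + 9)] <- fs / 10
  ev <- data.frame(onset_s = 1, offset_s = 1.01, velocity_khz_per_ms = 1.59)
  out <- score_rvf(rate_function(lam, fs), ev)
  expect_equal(out$rate, 1 / 0.015, tolerance = 1e-6)
  # all-zero record scores zero
  expect_equal(score_rvf(rate_function(numeric(2 * fs), fs), ev)$rate, 0)
  # events that run past the record are skipped with a warning
  ev2 <- rbind(ev, data.frame(onset_s = 1.99, offset_s = 2.0,
                              velocity_khz_per_ms = 1.59))
  expect_warning(score_rvf(rate_function(lam, fs), ev2), "skipping")
})

test_that("direction bias is the signed per-speed contrast", {
  cv <- response_curve(c(-1.59, -0.4, 0.4, 1.59), c(10, 0, 0, 30),
                       kind = "RVF")
  b <- direction_bias(cv)
  expect_equal(b$bias[b$speed == 0.4], 0)         # both zero -> 0
  expect_equal(b$bias[b$speed == 1.59], 0.5)      # (30-10)/40
  cv2 <- response_curve(c(-1, 1), c(0, 5), kind = "RVF")
  expect_equal(direction_bias(cv2)$bias, 1)
  expect_error(direction_bias(response_curve(c(1, 2), c(1, 1), kind = "RVF")),
               "paired")
  expect_error(direction_bias(response_curve(1:3, 1:3, kind = "MTF")), "RVF")
})

test_that("MTF classification finds contiguous enhancement and its BMF", {
  fms <- mtf_grid(10)
  flat <- classify_mtf(fms, rep(30, 10), 30)
  expect_equal(flat$label, "flat")
  expect_true(is.na(flat$bmf))
  be <- classify_mtf(fms, c(30, 30, 30, 40, 52, 44, 30, 30, 30, 30), 30)
  expect_equal(be$label, "band-enhanced")
  expect_equal(be$bmf, fms[5])
  bs <- classify_mtf(fms, c(30, 30, 20, 18, 22, 30, 30, 30, 30, 30), 30)
  expect_equal(bs$label, "band-suppressed")
  # classification is invariant to uniform rate scaling
  be2 <- classify_mtf(fms, 3.7 * c(30, 30, 30, 40, 52, 44, 30, 30, 30, 30),
                      3.7 * 30)
  expect_equal(be2$label, "band-enhanced")
  expect_equal(be2$bmf, be$bmf)
  # isolated single-point excursions do not qualify
  spike <- classify_mtf(fms, c(30, 30, 60, 30, 30, 30, 30, 30, 30, 30), 30)
  expect_equal(spike$label, "other")
})

test_that("response map flags a silent model and estimates CF for a live
           one", {
  register_an_backend("silent", function(w, cf, seed = NULL, n_avg = 1,
                                         spont = 60, ...)
    rate_function(numeric(length(w$samples)), w$fs))
  m_silent <- cd_model(octopus_params(4000, 5330), fs = 2e4,
                       backend = "silent")
  rm0 <- response_map(m_silent, freqs = c(1000, 4000), levels = c(30, 70),
                      stage = "oct", dur = 0.05)
  expect_true(is.na(rm0$cf))
  # octopus-stage map for the 4-kHz preset peaks near its CF
  m <- fast_model("cf4k_down", fs = 5e4)
  freqs <- rm_freq_grid(10)
  rm1 <- response_map(m, freqs = freqs, levels = c(30, 50, 70), stage = "oct",
                      dur = 0.1, seed = 2)
  expect_false(is.na(rm1$cf))
  ratio <- rm1$cf / 4000
  step <- freqs[2] / freqs[1]
  expect_lt(abs(log(ratio)), log(step))  # within one grid step of 4 kHz
})

test_that("multi-trial RVFs carry well-formed rates and spreads", {
  m <- preset_model("cf4k_down", fs = 5e4, noise_cv = 0.5)
  spec <- chirp_train_spec(n_reps = 3, seed = 8)
  ro <- suppressWarnings(rvf(m, spec, stage = "oct", reps = 3, seed = 4))
  ri <- suppressWarnings(rvf(m, spec, stage = "ic", reps = 3, seed = 4))
  expect_equal(ro$x, sort(chirp_velocities()))
  expect_true(all(ro$rate >= 0) && all(ri$rate >= 0))
  expect_true(all(is.finite(ro$spread)) && all(ro$spread >= 0))
  expect_true(all(is.finite(ri$spread)) && all(ri$spread >= 0))
  # trial noise actually propagates to the curves
  expect_gt(max(c(ro$spread, ri$spread)), 0)
  # identical master seed reproduces the curve exactly
  ro2 <- suppressWarnings(rvf(m, spec, stage = "oct", reps = 3, seed = 4))
  expect_identical(ro$rate, ro2$rate)
})
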