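test_that("surrogate channel baseline, determinism and nonnegativity", {
  fs <- 5e4
  sil <- waveform(numeric(fs / 5), fs)
  r <- surrogate_an(sil, 4000)
  expect_equal(r$lam, rep(60, length(r$lam)))
  w <- make_tone(2000, 0.1, 60, fs)
  r1 <- surrogate_an(w, 2000, seed = 9, n_avg = 3)
  r2 <- surrogate_an(w, 2000, seed = 9, n_avg = 3)
  expect_identical(r1$lam, r2$lam)
  expect_true(all(r1$lam >= 0))
  set.seed(2)
  wild <- waveform(rnorm(5000) * 10, fs)
  expect_true(all(is.finite(surrogate_an(wild, 3000)$lam)))
})

test_that("CF tone responses show onset emphasis and saturation", {
  fs <- 1e5
  w <- make_tone(4000, 0.2, 70, fs)
  r <- surrogate_an(w, 4000)
  sus_idx <- round(0.1 * fs):round(0.19 * fs)
  sus <- mean(r$lam[sus_idx])
  expect_gt(max(r$lam), sus)                 # onset peak above steady state
  expect_gt(sus, 150); expect_lt(sus, 320)   # HSR-like saturated rate
  # doubling the amplitude at saturation changes the sustained rate < 10%
  r6 <- surrogate_an(make_tone(4000, 0.2, 76, fs), 4000)
  expect_lt(abs(mean(r6$lam[sus_idx]) - sus) / sus, 0.1)
})

test_that("click response latency decreases monotonically with CF", {
  fs <- 1e5
  ck <- make_click_train(2, dur = 0.4, fs = fs)
  # onset latency = first crossing of 20% of the driven peak
  lat <- vapply(c(500, 1000, 2000, 4000, 8000, 10000), function(cf) {
    r <- surrogate_an(ck, cf)
    which(r$lam > 60 + 0.2 * (max(r$lam) - 60))[1]
  }, integer(1))
  # strictly decreasing until the synaptic-filter rise time floors it
  expect_true(all(diff(lat[1:4]) < 0))
  expect_true(all(diff(lat) <= 0))
})

test_that("fiber averaging shrinks trial variance roughly as 1/n", {
  fs <- 5e4
  w <- make_sam_noise(40, dur = 0.2, fs = fs, seed = 5)
  spread <- function(n_avg) {
    rates <- vapply(1:8, function(k)
      mean(surrogate_an(w, 3000, seed = 100 + k, n_avg = n_avg)$lam),
      numeric(1))
    var(rates)
  }
  expect_gt(spread(1) / spread(10), 3)
})

test_that("the backend registry dispatches and rejects unknown names", {
  expect_error(an_backend("no-such-model"), "unknown AN backend")
  register_an_backend("half-spont", function(w, cf, seed = NULL, n_avg = 1,
                                             spont = 60, ...)
    rate_function(rep(spont / 2, length(w$samples)), w$fs))
  w <- waveform(numeric(1000), 1e4)
  out <- an_rate(w, an_channel_spec(1000), backend = "half-spont")
  expect_equal(out$lam, rep(30, 1000))
})
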