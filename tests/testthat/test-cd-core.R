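test_that("window integrals follow the rectangular rule with clamping", {
  x <- constant_rate(100, dur = 0.1, fs = 1e4)
  y <- window_integral(x, 1e-3)
  expect_equal(steady(y), 0.1, tolerance = 1e-9)
  expect_equal(window_integral(constant_rate(0, fs = 1e4), 1e-3),
               rep(0, 5000))
  # expected counts above 1 are clamped so survival factors stay in [0, 1]
  expect_equal(steady(window_integral(constant_rate(2000, fs = 1e4), 1e-3)), 1)
  # partial sums before one full window
  expect_equal(y[5], 5 * 100 / 1e4, tolerance = 1e-9)
  expect_error(window_integral(x, 1e-5), "sample period")
})

test_that("shift_rate delays by whole samples with zero fill", {
  x <- rate_function(c(1, 2, 3, 4), 1000)
  expect_equal(shift_rate(x, 2e-3)$lam, c(0, 0, 1, 2))
  expect_identical(shift_rate(x, 0), x)
  expect_error(shift_rate(x, -1e-3), "nonnegative")
})

test_that("EE all-active matches the closed form and is symmetric", {
  r <- constant_rate(100, fs = 1e4)
  out <- ee_all_active(list(r, r), 1e-3)
  expect_equal(steady(out), 2 * 100 * (100 * 1e-3), tolerance = 1e-4)
  # an always-silent input annihilates the product
  z <- constant_rate(0, fs = 1e4)
  expect_equal(max(ee_all_active(list(r, r, z), 1e-3)$lam), 0)
  # permutation symmetry
  a <- constant_rate(80, fs = 1e4); b <- constant_rate(150, fs = 1e4)
  expect_equal(ee_all_active(list(a, b, r), 1e-3)$lam,
               ee_all_active(list(r, a, b), 1e-3)$lam)
  expect_error(ee_all_active(list(r), 1e-3), "at least 2")
  expect_error(ee_all_active(list(r, constant_rate(1, dur = 0.1, fs = 1e4)),
                             1e-3), "share")
})

test_that("inactive-set survival factors multiply as expected", {
  r <- constant_rate(100, fs = 1e4)
  expect_identical(inactive_term(list(), 1e-3), 1)
  expect_equal(steady(inactive_term(list(constant_rate(0, fs = 1e4)), 1e-3)), 1)
  expect_equal(steady(inactive_term(list(r), 1e-3)), 0.9, tolerance = 1e-9)
  expect_equal(steady(inactive_term(list(r, r), 1e-3)), 0.81, tolerance = 1e-9)
})

test_that("exactly-l EE reduces correctly and matches the closed form", {
  r <- constant_rate(100, fs = 1e4)
  ins <- list(r, r, r)
  expect_equal(ee_exactly_l(ins, 3, 1e-3)$lam,
               ee_all_active(ins, 1e-3)$lam)
  # 3 subsets x [2r(r delta)] x (1 - r delta) = 54 spikes/s
  expect_equal(steady(ee_exactly_l(ins, 2, 1e-3)), 54, tolerance = 1e-4)
  expect_error(ee_exactly_l(ins, 1, 1e-3), "2 <= l")
  expect_error(ee_exactly_l(ins, 4, 1e-3), "2 <= l")
  z <- constant_rate(0, fs = 1e4)
  expect_equal(max(ee_exactly_l(list(r, r, z), 3, 1e-3)$lam), 0)
})

test_that("EI inhibition gates excitation by survival powers", {
  exc <- constant_rate(100, fs = 1e4)
  inh <- constant_rate(100, fs = 1e4)
  expect_identical(ei_inhibit(exc, inh, 1e-3, 0), exc)
  expect_equal(ei_inhibit(exc, constant_rate(0, fs = 1e4), 1e-3, 5)$lam,
               exc$lam)
  expect_equal(steady(ei_inhibit(exc, inh, 1e-3, 2)), 81, tolerance = 1e-6)
  # monotone in m and in inhibitory rate, pointwise
  m_seq <- vapply(0:6, function(m)
    steady(ei_inhibit(exc, inh, 1e-3, m)), numeric(1))
  expect_true(all(diff(m_seq) < 0))
  r_seq <- vapply(c(50, 100, 200, 400), function(ri)
    steady(ei_inhibit(exc, constant_rate(ri, fs = 1e4), 1e-3, 3)), numeric(1))
  expect_true(all(diff(r_seq) < 0))
  expect_error(ei_inhibit(exc, inh, 1e-3, 1.5), "integer")
})

test_that("closed forms hold across random constant-rate ensembles", {
  set.seed(7)
  for (i in 1:20) {
    r1 <- runif(1, 20, 190); r2 <- runif(1, 20, 190)
    delta <- sample(c(5e-4, 1e-3), 1)
    a <- constant_rate(r1, fs = 2e4); b <- constant_rate(r2, fs = 2e4)
    expect_equal(steady(ee_all_active(list(a, b), delta)),
                 r1 * r2 * delta + r2 * r1 * delta, tolerance = 1e-3)
    m <- sample(0:12, 1)
    expect_equal(steady(ei_inhibit(a, b, delta, m)),
                 r1 * (1 - r2 * delta)^m, tolerance = 1e-3)
  }
})
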