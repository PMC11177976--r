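# Shared fixtures: synthetic rate functions and the independent Monte-Carlo
# Poisson coincidence oracle used to cross-check the coincidence-detector
# algebra.

constant_rate <- function(r, dur = 0.5, fs = 1e4) {
  rate_function(rep(r, round(dur * fs)), fs)
}

gauss_pulse_rate <- function(amp, t0, sigma, dur = 0.02, fs = 1e5) {
  t <- (seq_len(round(dur * fs)) - 1) / fs
  rate_function(amp * exp(-(t - t0)^2 / (2 * sigma^2)), fs)
}

# Steady-state value of a rate function / numeric series (mean of last 20%).
steady <- function(x) {
  v <- if (inherits(x, "rate_function")) x$lam else x
  n <- length(v)
  mean(v[ceiling(0.8 * n):n])
}

# Homogeneous Poisson spike train on [0, dur].
sim_poisson <- function(rate, dur) {
  n <- stats::rpois(1, rate * dur * 1.25 + 20)
  s <- cumsum(stats::rexp(n, rate))
  s[s < dur]
}

# Monte-Carlo estimate of the exactly-l coincidence rate for constant-rate
# Poisson inputs. For each spike on a distinguished input the contribution is
# the sum over active subsets containing it of the product of window *counts*
# on the other active inputs times prod(1 - count) on the inactive inputs --
# an unbiased estimator of the expected-count algebra the model defines.
# Returns the estimate and a batch-means standard error.
mc_exactly_l <- function(rates, l, delta, dur = 200, seed = 1, n_batch = 25) {
  set.seed(seed)
  N <- length(rates)
  trains <- lapply(rates, sim_poisson, dur = dur)
  win_count <- function(tt, s) findInterval(tt, s) - findInterval(tt - delta, s)
  subsets <- utils::combn(N, l, simplify = FALSE)
  ev_t <- numeric(0); ev_w <- numeric(0)
  for (i in seq_len(N)) {
    tt <- trains[[i]]
    if (!length(tt)) next
    cnt <- vapply(seq_len(N), function(j)
      if (j == i) rep(NA_real_, length(tt)) else win_count(tt, trains[[j]]),
      numeric(length(tt)))
    w <- numeric(length(tt))
    for (S in subsets) {
      if (!(i %in% S)) next
      term <- rep(1, length(tt))
      for (j in setdiff(S, i)) term <- term * cnt[, j]
      for (j in setdiff(seq_len(N), S)) term <- term * (1 - cnt[, j])
      w <- w + term
    }
    ev_t <- c(ev_t, tt); ev_w <- c(ev_w, w)
  }
  batch <- findInterval(ev_t, seq(0, dur, length.out = n_batch + 1),
                        rightmost.closed = TRUE)
  per_batch <- vapply(seq_len(n_batch), function(b)
    sum(ev_w[batch == b]) / (dur / n_batch), numeric(1))
  list(rate = sum(ev_w) / dur, se = stats::sd(per_batch) / sqrt(n_batch))
}

mc_all_active <- function(rates, delta, dur = 200, seed = 1) {
  mc_exactly_l(rates, length(rates), delta, dur, seed)
}

# Fast small model used by characterization tests.
fast_model <- function(preset = "cf4k_down", fs = 5e4, noise_cv = 0, ...) {
  preset_model(preset, fs = fs, noise_cv = noise_cv, ...)
}
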