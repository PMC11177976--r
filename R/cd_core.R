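# Coincidence-detector algebra on instantaneous-rate functions: trailing
# window integrals, excitatory-excitatory (EE) all-active and exactly-l
# interactions with inactive sets, and excitatory-inhibitory (EI) survival
# multiplication.

#' Trailing window integral of a rate function
#'
#' Computes `y(t) = integral of lambda over (t - delta, t]` by the
#' rectangular rule at the native sample rate, clamped to `[0, 1]` so that
#' the probabilistic survival factors `1 - y` stay in `[0, 1]` (realistic
#' auditory-nerve rates violate `integral <= 1` over the millisecond-scale
#' windows used by the model; clamping is the minimal fix and is documented
#' in the methods vignette). For `t < delta` the partial sum from the start
#' of the record is used.
#'
#' @param x A [rate_function()].
#' @param delta Window length in seconds; at least one sample period.
#' @return Numeric vector (unitless expected counts) of the same length.
#' @export
window_integral <- function(x, delta) {
  dt <- 1 / x$fs
  k <- round(delta * x$fs)
  if (k < 1) stop_invalid("`delta` must be at least one sample period")
  cs <- cumsum(x$lam) * dt
  n <- length(cs)
  y <- cs
  if (k < n) y[(k + 1):n] <- cs[(k + 1):n] - cs[1:(n - k)]
  pmin(pmax(y, 0), 1)
}

#' Delay a rate function
#'
#' Shifts the rate function later in time by `delay` seconds (rounded to the
#' nearest whole sample), zero-filling at the start and truncating at the
#' end so length is preserved.
#'
#' @param x A [rate_function()].
#' @param delay Nonnegative delay in seconds.
#' @return A [rate_function()].
#' @export
shift_rate <- function(x, delay) {
  if (!is_scalar_num(delay) || delay < 0)
    stop_invalid("`delay` must be nonnegative")
  k <- round(delay * x$fs)
  if (k == 0) return(x)
  n <- length(x$lam)
  if (k >= n) return(rate_function(numeric(n), x$fs))
  rate_function(c(numeric(k), x$lam[1:(n - k)]), x$fs)
}

#' EE coincidence rate, all inputs active
#'
#' Output rate of a coincidence detector that responds at `t` only when
#' activity is observed on all `N` inputs within `(t - delta, t]`:
#' `lambda_EE(t) = sum_l lambda_l(t) * prod_{j != l} W_j(t)` where `W_j` is
#' the trailing [window_integral()].
#'
#' @param inputs List of two or more [rate_function()]s sharing sample rate
#'   and length.
#' @param delta EE integration window in seconds.
#' @return A [rate_function()].
#' @export
ee_all_active <- function(inputs, delta) {
  if (length(inputs) < 2L) stop_invalid("need at least 2 inputs")
  check_aligned(inputs)
  W <- lapply(inputs, window_integral, delta = delta)
  n <- length(inputs[[1]]$lam)
  out <- numeric(n)
  for (l in seq_along(inputs)) {
    term <- inputs[[l]]$lam
    for (j in seq_along(inputs)) if (j != l) term <- term * W[[j]]
    out <- out + term
  }
  rate_function(out, inputs[[1]]$fs)
}

#' Survival factor of a set of inactive inputs
#'
#' `prod_j (1 - W_j(t))` over the inactive set; the empty product is 1.
#'
#' @param omega List (possibly empty) of [rate_function()]s.
#' @param delta Integration window in seconds.
#' @return Numeric vector (or scalar 1 for an empty set).
#' @export
inactive_term <- function(omega, delta) {
  if (length(omega) == 0L) return(1)
  check_aligned(omega)
  out <- 1
  for (x in omega) out <- out * (1 - window_integral(x, delta))
  out
}

#' EE coincidence rate, exactly l of N inputs active
#'
#' Sum over all `choose(N, l)` active subsets of the all-active EE rate of
#' the subset times the survival factor of its complement.
#'
#' @param inputs List of `N >= 2` aligned [rate_function()]s.
#' @param l Number of active inputs required, `2 <= l <= N`.
#' @param delta EE integration window in seconds.
#' @return A [rate_function()].
#' @export
ee_exactly_l <- function(inputs, l, delta) {
  N <- length(inputs)
  if (!is_count(l) || l < 2 || l > N)
    stop_invalid("`l` must satisfy 2 <= l <= length(inputs)")
  check_aligned(inputs)
  fs <- inputs[[1]]$fs
  sets <- combn(N, l, simplify = FALSE)
  out <- numeric(length(inputs[[1]]$lam))
  for (idx in sets) {
    active <- ee_all_active(inputs[idx], delta)$lam
    inact <- inactive_term(inputs[-idx], delta)
    out <- out + active * inact
  }
  rate_function(out, fs)
}

#' EI interaction: excitation gated by inhibitory survival
#'
#' `out(t) = exc(t) * (1 - W_inh(t))^m` where `W_inh` is the trailing window
#' integral of the inhibitory input delayed by `delay`. The exponent `m` is
#' the number of duplicated independent inhibitory inputs.
#'
#' @param exc Excitatory [rate_function()].
#' @param inh Inhibitory [rate_function()].
#' @param delta Inhibitory integration window in seconds.
#' @param m Nonnegative integer number of inhibitory copies; `m = 0` returns
#'   the excitation unchanged.
#' @param delay Nonnegative delay applied to the inhibitory input, seconds.
#' @return A [rate_function()].
#' @export
ei_inhibit <- function(exc, inh, delta, m, delay = 0) {
  if (!is_count(m)) stop_invalid("`m` must be a nonnegative integer")
  check_aligned(list(exc, inh))
  if (m == 0) return(exc)
  W <- window_integral(shift_rate(inh, delay), delta)
  rate_function(exc$lam * (1 - W)^m, exc$fs)
}
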