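#' Octopus-cell stage parameters
#'
#' Parameters of the sequence-detecting octopus-cell stage: `n_cf` identical
#' copies of the on-CF (suprathreshold) auditory-nerve input plus one off-CF
#' (subthreshold) input form an at-least-(N-1)-of-N EE coincidence detector
#' with window `delta_ee`; delayed copies of both excitatory inputs act as
#' "hyperpolarization" inhibition (window `delta_hyp`, delay `d_hyp`)
#' standing in for low-voltage-activated potassium (KL) channel dynamics;
#' the output is thresholded at `theta` to give an ideal-onset response.
#' Whether `ocf` lies above or below `cf` sets the preferred chirp
#' direction (above = upward-selective).
#'
#' @param cf Characteristic frequency of the suprathreshold input, Hz.
#' @param ocf Off-CF input frequency, Hz; must differ from `cf`.
#' @param n_cf Number of identical CF input copies (`= L`, >= 2; typically
#'   3, or 4 for low-CF cells).
#' @param d_cf,d_ocf Alignment delays (s) of the CF / OCF inputs; at most
#'   one may be nonzero.
#' @param delta_ee EE integration window, s (default 1 ms).
#' @param delta_hyp Hyperpolarization integration window, s (default 2 ms).
#' @param d_hyp Hyperpolarization delay, s (default 0.4 ms).
#' @param theta Onset threshold, spikes/s (default 50).
#' @param n_ocf Number of OCF copies; fixed at 1 in this model.
#' @return An object of class `octopus_params`.
#' @export
octopus_params <- function(cf, ocf, n_cf = 3, d_cf = 0, d_ocf = 0,
                           delta_ee = 1e-3, delta_hyp = 2e-3,
                           d_hyp = 0.4e-3, theta = 50, n_ocf = 1) {
  if (!is_scalar_num(cf) || cf <= 0) stop_invalid("`cf` must be > 0")
  if (!is_scalar_num(ocf) || ocf <= 0 || ocf == cf)
    stop_invalid("`ocf` must be > 0 and different from `cf`")
  if (!is_count(n_cf, 2L)) stop_invalid("`n_cf` must be an integer >= 2")
  if (n_ocf != 1L) stop_invalid("`n_ocf` is fixed at 1 in this model")
  if (d_cf < 0 || d_ocf < 0) stop_invalid("delays must be nonnegative")
  if (d_cf > 0 && d_ocf > 0)
    stop_invalid("at most one of `d_cf`, `d_ocf` may be nonzero")
  if (!is_scalar_num(theta) || theta < 0) stop_invalid("`theta` must be >= 0")
  if (delta_ee <= 0 || delta_hyp <= 0 || d_hyp < 0)
    stop_invalid("windows must be positive and `d_hyp` nonnegative")
  structure(list(cf = cf, ocf = ocf, n_cf = as.integer(n_cf),
                 n_ocf = 1L, d_cf = d_cf, d_ocf = d_ocf,
                 delta_ee = delta_ee, delta_hyp = delta_hyp, d_hyp = d_hyp,
                 theta = theta),
            class = "octopus_params")
}

#' Octopus-cell stage rate function
#'
#' Computes the octopus-cell output from the CF and OCF auditory-nerve rate
#' functions:
#' 1. delay the inputs by `d_cf` / `d_ocf`;
#' 2. form the at-least-(N-1)-of-N EE rate as the sum of the exactly-N and
#'    exactly-(N-1) terms over the `n_cf` CF copies plus the OCF input,
#'    window `delta_ee`;
#' 3. multiply by the two hyperpolarization survival factors
#'    `1 - integral over delta_hyp` of each (already-delayed) excitatory
#'    input further delayed by `d_hyp` -- the hyperpolarization tracks the
#'    excitation that causes it;
#' 4. set all samples below `theta` to zero (ideal-onset thresholding).
#'
#' The result responds preferentially when the suprathreshold CF input leads
#' the subthreshold OCF input (sequence detection).
#'
#' @param lam_cf,lam_ocf [rate_function()]s of the CF and OCF channels,
#'   sharing sample rate and length.
#' @param p An [octopus_params()].
#' @return A [rate_function()]; every sample is either 0 or >= `theta`.
#' @export
octopus_response <- function(lam_cf, lam_ocf, p) {
  stopifnot(inherits(p, "octopus_params"))
  check_aligned(list(lam_cf, lam_ocf))
  s_cf <- shift_rate(lam_cf, p$d_cf)
  s_ocf <- shift_rate(lam_ocf, p$d_ocf)
  inputs <- c(rep(list(s_cf), p$n_cf), list(s_ocf))
  N <- p$n_cf + 1L
  lam_ee <- ee_exactly_l(inputs, N, p$delta_ee)$lam +
    ee_exactly_l(inputs, N - 1L, p$delta_ee)$lam
  surv_cf <- 1 - window_integral(shift_rate(s_cf, p$d_hyp), p$delta_hyp)
  surv_ocf <- 1 - window_integral(shift_rate(s_ocf, p$d_hyp), p$delta_hyp)
  out <- lam_ee * surv_cf * surv_ocf
  out[out < p$theta] <- 0
  rate_function(out, lam_cf$fs)
}
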