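#' IC stage parameters
#'
#' Parameters of the inferior-colliculus stage: CF excitation delayed by
#' `d_e`, same-frequency inhibition (SFIE) from a copy of the CF input
#' delayed by `d_i > d_e` with window `delta_i` duplicated `m_i` times, and
#' octopus-cell inhibition delayed by `d_oct` with window `delta_oct`
#' duplicated `m_oct` times. The octopus inhibition's lead over excitation
#' is realized by `d_e > 0` with `d_oct` defaulting to 0.
#'
#' @param d_e Excitatory delay, s (> 0).
#' @param d_i SFIE inhibitory delay, s (> `d_e`); `d_i - d_e` sets the best
#'   modulation frequency of the band-enhanced MTF.
#' @param m_i Number of duplicated SFIE inhibitory inputs (>= 0).
#' @param m_oct Number of duplicated octopus inhibitory inputs (>= 0);
#'   controls chirp-direction sensitivity.
#' @param delta_i,delta_oct Integration windows, s (default 1 ms each).
#' @param d_oct Octopus inhibition delay, s (default 0).
#' @return An object of class `ic_params`.
#' @export
ic_params <- function(d_e, d_i, m_i, m_oct, delta_i = 1e-3,
                      delta_oct = 1e-3, d_oct = 0) {
  if (!is_scalar_num(d_e) || d_e <= 0) stop_invalid("`d_e` must be > 0")
  if (!is_scalar_num(d_i) || d_i <= d_e)
    stop_invalid("`d_i` must be greater than `d_e`")
  if (!is_count(m_i) || !is_count(m_oct))
    stop_invalid("`m_i` and `m_oct` must be nonnegative integers")
  if (delta_i <= 0 || delta_oct <= 0)
    stop_invalid("integration windows must be positive")
  if (d_oct < 0) stop_invalid("`d_oct` must be nonnegative")
  structure(list(d_e = d_e, d_i = d_i, delta_i = delta_i,
                 m_i = as.integer(m_i), d_oct = d_oct,
                 delta_oct = delta_oct, m_oct = as.integer(m_oct)),
            class = "ic_params")
}

#' IC stage rate function
#'
#' `lambda_IC(t) = lambda_CF(t - d_e) *
#'   (1 - integral over delta_i of lambda_CF(t - d_i))^m_i *
#'   (1 - integral over delta_oct of lambda_Oct(t - d_oct))^m_oct`,
#' half-wave rectified. The SFIE survival factor produces band-enhanced AM
#' tuning; the octopus survival factor transfers (inverted) chirp-direction
#' selectivity.
#'
#' @param lam_cf CF auditory-nerve [rate_function()] (excitation and SFIE
#'   inhibition source).
#' @param lam_oct Octopus-stage [rate_function()].
#' @param p An [ic_params()].
#' @return A [rate_function()].
#' @export
ic_response <- function(lam_cf, lam_oct, p) {
  stopifnot(inherits(p, "ic_params"))
  check_aligned(list(lam_cf, lam_oct))
  exc <- shift_rate(lam_cf, p$d_e)
  out <- ei_inhibit(exc, lam_cf, p$delta_i, p$m_i, p$d_i)
  out <- ei_inhibit(out, lam_oct, p$delta_oct, p$m_oct, p$d_oct)
  rate_function(pmax(out$lam, 0), lam_cf$fs)
}
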