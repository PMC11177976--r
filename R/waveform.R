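#' Calibrated pressure waveform
#'
#' Container for a sound-pressure time series. Samples are in pascals (Pa),
#' so that sound levels in dB SPL (re 20 micropascal) can be measured from,
#' and imposed on, the waveform directly.
#'
#' @param samples Numeric vector of sound pressure in Pa. All values must be
#'   finite.
#' @param fs Sample rate in Hz (> 0).
#' @param t0 Start time in seconds (default 0).
#' @return An object of class `waveform` with fields `samples`, `fs`, `t0`.
#' @examples
#' w <- waveform(sin(2 * pi * 100 * seq(0, 0.1, by = 1e-4)), fs = 1e4)
#' wave_duration(w)
#' @export
waveform <- function(samples, fs, t0 = 0) {
  if (!is_scalar_num(fs) || fs <= 0) stop_invalid("`fs` must be a positive number")
  if (!is.numeric(samples) || anyNA(samples) || any(!is.finite(samples)))
    stop_invalid("`samples` must be finite numeric")
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.4g s), level %.1f dB SPL\n",
              length(x$samples), x$fs, wave_duration(x),
              tryCatch(measure_level(x), error = function(e) NA_real_)))
  invisible(x)
}

#' Waveform duration in seconds
#' @param w A [waveform()].
#' @export
wave_duration <- function(w) length(w$samples) / w$fs

#' Measure overall sound level of a waveform
#'
#' Overall level in dB SPL: `20 * log10(rms / 20e-6)` with RMS taken over the
#' whole waveform.
#'
#' @param w A [waveform()].
#' @return Level in dB SPL.
#' @export
measure_level <- function(w) {
  r <- sqrt(mean(w$samples^2))
  if (r == 0) stop_invalid("cannot measure the level of an all-zero waveform")
  20 * log10(r / 20e-6)
}

#' Scale a waveform to a target overall level
#'
#' Rescales the samples so that the overall RMS equals
#' `20e-6 * 10^(level / 20)` Pa, i.e. the requested level in dB SPL re
#' 20 micropascal.
#'
#' @param w A [waveform()].
#' @param level Target overall level in dB SPL.
#' @return The rescaled [waveform()].
#' @export
set_level <- function(w, level) {
  r <- sqrt(mean(w$samples^2))
  if (r == 0) stop_invalid("cannot set the level of an all-zero waveform")
  target <- 20e-6 * 10^(level / 20)
  waveform(w$samples * (target / r), w$fs, w$t0)
}

#' Apply raised-cosine onset/offset ramps
#'
#' Multiplies the first and last `ramp_dur` seconds of the waveform by
#' raised-cosine (hann-shaped) envelopes rising from 0 to 1 (onset) and
#' falling from 1 to 0 (offset). The interior and the total duration are
#' unchanged.
#'
#' @param w A [waveform()].
#' @param ramp_dur Ramp duration in seconds; `2 * ramp_dur` must not exceed
#'   the waveform duration.
#' @return The ramped [waveform()].
#' @export
apply_ramp <- function(w, ramp_dur) {
  if (!is_scalar_num(ramp_dur) || ramp_dur < 0)
    stop_invalid("`ramp_dur` must be a nonnegative number")
  n <- length(w$samples)
  nr <- round(ramp_dur * w$fs)
  if (nr <= 1) return(w)
  if (2 * nr > n)
    stop_invalid("ramp duration exceeds half the waveform duration")
  env <- 0.5 * (1 - cos(pi * (seq_len(nr) - 1) / (nr - 1)))
  s <- w$samples
  s[seq_len(nr)] <- s[seq_len(nr)] * env
  s[seq(n - nr + 1, n)] <- s[seq(n - nr + 1, n)] * rev(env)
  waveform(s, w$fs, w$t0)
}

#' Export a waveform as CSV
#'
#' Writes two columns, `time_s` and `pressure_pa`.
#'
#' @param w A [waveform()].
#' @param path Output file path.
#' @export
write_waveform_csv <- function(w, path) {
  df <- data.frame(time_s = w$t0 + (seq_along(w$samples) - 1) / w$fs,
                   pressure_pa = w$samples)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
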