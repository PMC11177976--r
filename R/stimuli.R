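# Calibrated stimulus battery: tones, SAM noise, click trains and aperiodic
# linear-chirp sequences (Schroeder-phase period construction).

#' Standard signed chirp-velocity set
#'
#' The twelve signed velocities (kHz/ms) used throughout for rate-velocity
#' functions: +/- 0.40, 0.80, 1.59, 3.16, 6.24 and 9.24 kHz/ms. Positive
#' velocities sweep upward.
#' @return Numeric vector of length 12, ascending.
#' @export
chirp_velocities <- function() {
  v <- c(0.40, 0.80, 1.59, 3.16, 6.24, 9.24)
  sort(c(-v, v))
}

#' Specification of an aperiodic chirp sequence
#'
#' Bundles the construction parameters of the aperiodic chirp stimulus: the
#' signed velocity set, the number of presentations per direction-by-velocity
#' condition, the bounds of the random silent gaps between chirps, and the
#' level/duration reference used for energy normalization. Each chirp is one
#' fundamental period of a Schroeder-phase complex, i.e. a linear frequency
#' sweep from the fundamental F0 to `f_top`, where F0 solves
#' `(f_top - F0) * F0 = |velocity|` (velocity in Hz^2 when expressed in
#' kHz/ms). The chirp level is `ref_level - 10*log10(T / T_ref)` with `T` the
#' chirp duration, which equalizes energy across velocities.
#'
#' @param velocities Signed velocities in kHz/ms, symmetric about 0.
#' @param n_reps Presentations per condition (default 42).
#' @param gap_range Bounds (s) of the uniform random silent gap between chirp
#'   offset and next onset (default 40--60 ms).
#' @param ref_level Reference level in dB SPL (default 65).
#' @param T_ref Reference chirp duration in s (default 2.5 ms, the duration of
#'   the +/-6.24 kHz/ms chirp).
#' @param f_top Upper sweep frequency in Hz (default 16 kHz).
#' @param seed RNG seed controlling presentation order and gaps.
#' @return An object of class `chirp_train_spec`.
#' @export
chirp_train_spec <- function(velocities = chirp_velocities(), n_reps = 42,
                             gap_range = c(0.04, 0.06), ref_level = 65,
                             T_ref = 2.5e-3, f_top = 16000, seed = 1) {
  if (!is_count(n_reps, 1L)) stop_invalid("`n_reps` must be a positive integer")
  if (length(gap_range) != 2L || gap_range[1] > gap_range[2] || gap_range[1] < 0)
    stop_invalid("`gap_range` must be c(low, high) with 0 <= low <= high")
  if (!is_scalar_num(T_ref) || T_ref <= 0) stop_invalid("`T_ref` must be > 0")
  vs <- sort(velocities)
  if (!isTRUE(all.equal(vs, sort(-velocities))) || any(velocities == 0))
    stop_invalid("`velocities` must be nonzero and symmetric about 0")
  structure(list(velocities = vs, n_reps = n_reps, gap_range = gap_range,
                 ref_level = ref_level, T_ref = T_ref, f_top = f_top,
                 seed = seed),
            class = "chirp_train_spec")
}

#' Fundamental frequency of the chirp construction
#'
#' Solves `(f_top - F0) * F0 = |velocity|` (velocity converted to Hz/s) for
#' the fundamental `F0` of the parent Schroeder-phase complex, taking the
#' smaller root so that the chirp duration is `1 / F0`.
#'
#' @param velocity Signed chirp velocity in kHz/ms.
#' @param f_top Upper sweep frequency in Hz.
#' @return `F0` in Hz.
#' @export
chirp_f0 <- function(velocity, f_top = 16000) {
  v <- abs(velocity) * 1e6  # kHz/ms -> Hz/s
  disc <- f_top^2 - 4 * v
  if (disc < 0)
    stop_invalid("no fundamental-frequency solution: |velocity| too high for f_top")
  (f_top - sqrt(disc)) / 2
}

#' Synthesize one aperiodic chirp
#'
#' A single linear-frequency cosine sweep between the fundamental `F0` and
#' `f_top` (upward for positive velocity, downward for negative), of duration
#' `1 / F0`, with raised-cosine ramps of 10% of the duration and level
#' `ref_level - 10*log10(T / T_ref)` dB SPL.
#'
#' @param velocity Signed velocity in kHz/ms.
#' @param spec A [chirp_train_spec()] carrying `f_top`, `ref_level`, `T_ref`.
#' @param fs Sample rate in Hz.
#' @return A [waveform()].
#' @export
make_chirp <- function(velocity, spec = chirp_train_spec(), fs = 1e5) {
  f0 <- chirp_f0(velocity, spec$f_top)
  Tdur <- 1 / f0
  n <- round(Tdur * fs)
  t <- (seq_len(n) - 1) / fs
  k <- (spec$f_top - f0) / Tdur              # sweep rate, Hz/s
  if (velocity > 0) {
    phase <- 2 * pi * (f0 * t + 0.5 * k * t^2)
  } else {
    phase <- 2 * pi * (spec$f_top * t - 0.5 * k * t^2)
  }
  w <- waveform(cos(phase), fs)
  w <- apply_ramp(w, 0.1 * Tdur)
  set_level(w, spec$ref_level - 10 * log10(Tdur / spec$T_ref))
}

#' Pure tone with raised-cosine ramps
#'
#' @param freq Tone frequency in Hz; must be below the Nyquist frequency.
#' @param dur Duration in s (default 200 ms).
#' @param level Overall level in dB SPL.
#' @param fs Sample rate in Hz.
#' @param ramp_dur Ramp duration in s (default 10 ms).
#' @return A [waveform()].
#' @export
make_tone <- function(freq, dur = 0.2, level = 70, fs = 1e5, ramp_dur = 0.01) {
  if (freq >= fs / 2) stop_invalid("`freq` must be below the Nyquist frequency")
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  w <- waveform(sin(2 * pi * freq * t), fs)
  w <- set_level(w, level)
  apply_ramp(w, ramp_dur)
}

#' Sinusoidally amplitude-modulated Gaussian noise
#'
#' Gaussian noise band-limited to `band` (brick-wall in the frequency
#' domain), modulated by `1 + mod_depth * sin(2*pi*fm*t)`, ramped with 50-ms
#' raised cosines, and finally calibrated so the overall level equals
#' `spectrum_level + 10*log10(bandwidth)` dB SPL -- the overall level implied
#' by the requested spectrum level (dB SPL per Hz). With the default band of
#' 100 Hz -- 10 kHz and spectrum level 30 dB SPL this is 70 dB SPL overall.
#' `mod_depth = 0` yields the unmodulated reference at the same overall level.
#'
#' @param fm Modulation frequency in Hz.
#' @param mod_depth Modulation depth in `[0, 1]`; 1 = 100% modulated.
#' @param band Noise band `c(low, high)` in Hz, inside `(0, fs/2)`.
#' @param spectrum_level Spectrum level in dB SPL per Hz (default 30).
#' @param dur Duration in s (default 1).
#' @param fs Sample rate in Hz.
#' @param seed RNG seed for the noise token (`NULL` = current RNG state).
#' @param ramp_dur Ramp duration in s (default 50 ms).
#' @return A [waveform()].
#' @export
make_sam_noise <- function(fm, mod_depth = 1, band = c(100, 10000),
                           spectrum_level = 30, dur = 1, fs = 1e5,
                           seed = NULL, ramp_dur = 0.05) {
  if (!is_scalar_num(mod_depth) || mod_depth < 0 || mod_depth > 1)
    stop_invalid("`mod_depth` must be in [0, 1]")
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop_invalid("`band` must satisfy 0 < low < high < fs/2")
  n <- round(dur * fs)
  x <- local_seed(seed, rnorm(n))
  # brick-wall bandpass
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  X <- fft(x)
  X[f < band[1] | f > band[2]] <- 0i
  x <- Re(fft(X, inverse = TRUE)) / n
  bw <- band[2] - band[1]
  w <- waveform(x, fs)
  w <- set_level(w, spectrum_level + 10 * log10(bw))  # pre-modulation
  if (mod_depth > 0) {
    t <- (seq_len(n) - 1) / fs
    w$samples <- w$samples * (1 + mod_depth * sin(2 * pi * fm * t))
  }
  w <- apply_ramp(w, ramp_dur)
  set_level(w, spectrum_level + 10 * log10(bw))
}

#' Rarefaction click train
#'
#' Periodic negative-going rectangular pulses. Level is given in dB peSPL:
#' the peak pressure magnitude equals the peak of a sinusoid at that SPL,
#' `sqrt(2) * 20e-6 * 10^(level/20)` Pa.
#'
#' @param rate Click rate in Hz; `rate * click_dur` must be < 1 (no overlap).
#' @param click_dur Single-click duration in s (default 0.1 ms).
#' @param level Level in dB peSPL (default 130).
#' @param dur Train duration in s (default 1).
#' @param fs Sample rate in Hz.
#' @return A [waveform()].
#' @export
make_click_train <- function(rate, click_dur = 1e-4, level = 130, dur = 1,
                             fs = 1e5) {
  if (rate * click_dur >= 1) stop_invalid("clicks overlap: rate * click_dur >= 1")
  n <- round(dur * fs)
  nk <- max(1L, round(click_dur * fs))
  peak <- sqrt(2) * 20e-6 * 10^(level / 20)
  s <- numeric(n)
  n_clicks <- max(1L, floor(dur * rate + 1e-9))
  onsets <- (seq_len(n_clicks) - 1) / rate
  for (on in onsets) {
    i0 <- round(on * fs) + 1L
    idx <- i0:min(n, i0 + nk - 1L)
    s[idx] <- -peak
  }
  waveform(s, fs)
}

#' Randomized aperiodic chirp sequence
#'
#' Concatenates all direction-by-velocity conditions, each presented exactly
#' `n_reps` times in globally shuffled order, separated by silent gaps drawn
#' uniformly from `gap_range` (a leading gap precedes the first chirp). The
#' event log records onset, offset and velocity of every chirp.
#'
#' @param spec A [chirp_train_spec()].
#' @param fs Sample rate in Hz.
#' @return A list with elements `waveform` (a [waveform()]) and `events`
#'   (a data frame with columns `onset_s`, `offset_s`,
#'   `velocity_khz_per_ms`).
#' @export
make_chirp_sequence <- function(spec = chirp_train_spec(), fs = 1e5) {
  conds <- rep(spec$velocities, each = spec$n_reps)
  n_ev <- length(conds)
  ord <- local_seed(spec$seed, list(
    order = sample.int(n_ev),
    gaps = runif(n_ev + 1L, spec$gap_range[1], spec$gap_range[2])))
  conds <- conds[ord$order]
  chirps <- lapply(spec$velocities, make_chirp, spec = spec, fs = fs)
  names(chirps) <- as.character(spec$velocities)
  segs <- vector("list", 2L * n_ev + 1L)
  onset <- offset <- numeric(n_ev)
  t_cursor <- 0
  for (i in seq_len(n_ev)) {
    gap_n <- round(ord$gaps[i] * fs)
    ch <- chirps[[as.character(conds[i])]]$samples
    segs[[2L * i - 1L]] <- numeric(gap_n)
    segs[[2L * i]] <- ch
    onset[i] <- (t_cursor + gap_n) / fs
    offset[i] <- (t_cursor + gap_n + length(ch)) / fs
    t_cursor <- t_cursor + gap_n + length(ch)
  }
  # trailing gap so response-analysis segments never run past the record
  segs[[2L * n_ev + 1L]] <- numeric(round(ord$gaps[n_ev + 1L] * fs))
  list(waveform = waveform(unlist(segs), fs),
       events = data.frame(onset_s = onset, offset_s = offset,
                           velocity_khz_per_ms = conds))
}

#' Export an event log as CSV
#' @param events Event data frame from [make_chirp_sequence()].
#' @param path Output file path.
#' @export
write_events_csv <- function(events, path) {
  write.csv(events, path, row.names = FALSE)
  invisible(path)
}
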