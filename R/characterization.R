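# Response characterization: response maps, noise and click modulation
# transfer functions, rate-velocity functions, and derived statistics.

#' Labeled response curve
#'
#' A data frame with columns `x` (stimulus axis: tone frequency in Hz,
#' modulation/click frequency in Hz, or signed chirp velocity in kHz/ms),
#' `rate` (mean spikes/s) and `spread` (standard deviation across model
#' trials), carrying its `kind` ("RM-row", "MTF", "clickMTF" or "RVF") as an
#' attribute.
#'
#' @param x Axis values.
#' @param rate Mean rates, spikes/s (>= 0).
#' @param spread Per-x standard deviation (default `NA`).
#' @param kind Curve kind.
#' @return An object of classes `response_curve` and `data.frame`.
#' @export
response_curve <- function(x, rate, spread = NA_real_, kind = "MTF") {
  if (any(rate < 0)) stop_invalid("rates must be nonnegative")
  df <- data.frame(x = x, rate = rate, spread = spread)
  class(df) <- c("response_curve", "data.frame")
  attr(df, "kind") <- kind
  df
}

#' Mean rate of a rate function over a time window
#'
#' `(sum of lam * dt over [t0, t1]) / (t1 - t0)` -- the integral of the
#' model rate function over the window, expressed in spikes/s.
#'
#' @param lam A [rate_function()].
#' @param t0,t1 Window bounds in seconds; default the whole record.
#' @return Mean rate in spikes/s.
#' @export
mean_rate <- function(lam, t0 = 0, t1 = NULL) {
  n <- length(lam$lam)
  dur <- n / lam$fs
  if (is.null(t1)) t1 <- dur
  if (t0 >= t1 || t0 < 0 || t1 > dur + 1e-9)
    stop_invalid("require 0 <= t0 < t1 <= duration")
  i0 <- max(1L, floor(t0 * lam$fs) + 1L)
  i1 <- min(n, round(t1 * lam$fs))
  sum(lam$lam[i0:i1]) / lam$fs / (t1 - t0)
}

#' Default tone-frequency grid for response maps
#' @param n Number of frequencies (default 30), log-spaced 250 Hz -- 10 kHz.
#' @export
rm_freq_grid <- function(n = 30) exp(seq(log(250), log(10000), length.out = n))

#' Default modulation-frequency grid for MTFs
#' @param n Number of frequencies (default 25), log-spaced 2 -- 500 Hz
#'   (about 3 per octave).
#' @export
mtf_grid <- function(n = 25) exp(seq(log(2), log(500), length.out = n))

#' Default click-rate grid
#'
#' 2 -- 500 Hz per the click-train convention, extended to 900 Hz so the
#' fall-off above the entrainment limit is visible.
#' @export
click_rate_grid <- function() c(2, 50, 100, 200, 300, 400, 500, 600, 700, 800, 900)

#' Pure-tone response map with CF estimate
#'
#' Presents tones over a frequency-by-level grid, computes mean rates over
#' the stimulus duration, and estimates CF as the frequency of maximal
#' above-spontaneous excitation at the lowest level at which any frequency
#' is excited. "Excited" means `rate > 1.2 * spont + 1` spikes/s, where the
#' spontaneous rate of the probed stage is measured from a silence run.
#'
#' @param model A [cd_model()].
#' @param freqs Tone frequencies, Hz.
#' @param levels Sound levels, dB SPL (default 10, 30, 50, 70).
#' @param stage Stage to probe: `"oct"` (default), `"ic"`, `"an_cf"`.
#' @param seed Master seed.
#' @param dur Tone duration, s (default 200 ms).
#' @return A list with `curves` (data frame `freq`, `level`, `rate`),
#'   `cf` (estimated CF in Hz, or `NA` if never excited), `spont`
#'   (spikes/s), and `cf_level` (the level at which CF was read).
#' @export
response_map <- function(model, freqs = rm_freq_grid(),
                         levels = c(10, 30, 50, 70), stage = "oct",
                         seed = 1, dur = 0.2) {
  if (!length(freqs) || !length(levels)) stop_invalid("empty grid")
  silence <- waveform(numeric(round(dur * model$fs)), model$fs)
  spont <- mean_rate(simulate_model(model, silence, seed = seed,
                                    stages = stage)[[stage]])
  grid <- expand.grid(freq = freqs, level = sort(levels))
  seeds <- derive_seeds(seed, nrow(grid))
  grid$rate <- vapply(seq_len(nrow(grid)), function(i) {
    w <- make_tone(grid$freq[i], dur = dur, level = grid$level[i],
                   fs = model$fs)
    mean_rate(simulate_model(model, w, seed = seeds[[i]],
                             stages = stage)[[stage]])
  }, numeric(1))
  excited <- grid$rate > 1.2 * spont + 1
  cf <- NA_real_; cf_level <- NA_real_
  for (lev in sort(levels)) {
    sel <- grid$level == lev
    if (any(excited[sel])) {
      sub <- grid[sel & excited, ]
      cf <- sub$freq[which.max(sub$rate)]
      cf_level <- lev
      break
    }
  }
  list(curves = grid, cf = cf, spont = spont, cf_level = cf_level)
}

#' Classify an MTF shape
#'
#' Band-enhanced (BE) if at least `min_contig` contiguous tested modulation
#' frequencies have rate >= `enh_ratio` times the unmodulated-reference
#' rate; band-suppressed (BS) likewise with rates <= `1/enh_ratio` times
#' the reference; flat if every rate stays within those bounds; otherwise
#' "other". For a BE MTF the best modulation frequency (BMF) is the
#' frequency of maximal rate.
#'
#' @param fms Tested modulation frequencies, Hz.
#' @param rates Mean rates at `fms`, spikes/s.
#' @param unmod_rate Rate for the unmodulated reference, spikes/s.
#' @param enh_ratio Enhancement criterion ratio (default 1.2).
#' @param min_contig Minimum contiguous run length (default 2).
#' @return A list with `label` (one of "band-enhanced", "band-suppressed",
#'   "flat", "other"), `bmf` (Hz, `NA` unless band-enhanced) and
#'   `unmod_rate`.
#' @export
classify_mtf <- function(fms, rates, unmod_rate, enh_ratio = 1.2,
                         min_contig = 2) {
  stopifnot(length(fms) == length(rates))
  enh <- if (unmod_rate > 0) rates >= enh_ratio * unmod_rate else rates > 0
  sup <- if (unmod_rate > 0) rates <= unmod_rate / enh_ratio else rep(FALSE, length(rates))
  has_run <- function(flags) {
    r <- rle(flags)
    any(r$values & r$lengths >= min_contig)
  }
  label <- if (has_run(enh)) "band-enhanced"
  else if (has_run(sup)) "band-suppressed"
  else if (!any(enh) && !any(sup)) "flat"
  else "other"
  bmf <- if (label == "band-enhanced") fms[which.max(rates)] else NA_real_
  list(label = label, bmf = bmf, unmod_rate = unmod_rate)
}

#' Noise modulation transfer function
#'
#' Presents 100%-modulated SAM noise across `fms` (plus the unmodulated
#' reference), with a fresh noise token and fresh fiber noise per trial,
#' and returns mean rate versus modulation frequency together with the MTF
#' classification.
#'
#' @param model A [cd_model()].
#' @param fms Modulation frequencies, Hz.
#' @param reps Model trials per condition (default 5).
#' @param stage Stage to probe (default `"ic"`).
#' @param seed Master seed.
#' @param dur Stimulus duration, s (default 1).
#' @param mod_depth Modulation depth (default 1).
#' @param ... Further arguments to [make_sam_noise()].
#' @return A list with `curve` (a [response_curve()] of kind "MTF"),
#'   `unmod_rate`, `unmod_spread` and `classification` (see
#'   [classify_mtf()]).
#' @export
noise_mtf <- function(model, fms = mtf_grid(), reps = 5, stage = "ic",
                      seed = 1, dur = 1, mod_depth = 1, ...) {
  if (!is_count(reps, 1L)) stop_invalid("`reps` must be >= 1")
  conds <- c(fms, NA)  # NA = unmodulated reference
  seeds <- matrix(derive_seeds(seed, 2L * length(conds) * reps),
                  nrow = length(conds) * reps)
  rates <- matrix(NA_real_, length(conds), reps)
  k <- 0L
  for (i in seq_along(conds)) {
    for (r in seq_len(reps)) {
      k <- k + 1L
      w <- make_sam_noise(fm = if (is.na(conds[i])) 1 else conds[i],
                          mod_depth = if (is.na(conds[i])) 0 else mod_depth,
                          dur = dur, fs = model$fs, seed = seeds[[k, 1]], ...)
      rates[i, r] <- mean_rate(simulate_model(model, w, seed = seeds[[k, 2]],
                                              stages = stage)[[stage]])
    }
  }
  m <- rowMeans(rates)
  s <- apply(rates, 1, sd)
  nf <- length(fms)
  curve <- response_curve(fms, m[seq_len(nf)], s[seq_len(nf)], kind = "MTF")
  list(curve = curve, unmod_rate = m[nf + 1], unmod_spread = s[nf + 1],
       classification = classify_mtf(fms, m[seq_len(nf)], m[nf + 1]))
}

#' Count threshold crossings of a rate function
#'
#' Counts upward crossings of `threshold` with a refractory lockout: after
#' a counted crossing, further crossings within `refractory` seconds are
#' ignored. Used to approximate action potentials in click-train responses.
#'
#' @param lam A [rate_function()].
#' @param threshold Crossing threshold, spikes/s.
#' @param refractory Lockout period, s (> 0).
#' @return Integer crossing count.
#' @export
count_threshold_crossings <- function(lam, threshold, refractory) {
  if (!is_scalar_num(refractory) || refractory <= 0)
    stop_invalid("`refractory` must be > 0")
  x <- lam$lam
  up <- which(x >= threshold & c(-Inf, x[-length(x)]) < threshold)
  if (!length(up)) return(0L)
  t_up <- up / lam$fs
  count <- 1L
  last <- t_up[1]
  for (tt in t_up[-1]) {
    if (tt - last >= refractory) {
      count <- count + 1L
      last <- tt
    }
  }
  count
}

#' Click-train modulation transfer function (entrainment)
#'
#' Presents click trains across `rates` and counts threshold crossings of
#' the probed stage's trial-averaged rate function (threshold 110 spikes/s,
#' 1-ms refractory by default), reporting crossings per second; the rate
#' function analyzed is the mean over `reps` seeded trials, mirroring the
#' convention that rate functions are constructed as means over stimulus
#' repetitions. A stage entrains at a click rate when the crossing count
#' equals the click count.
#'
#' @param model A [cd_model()].
#' @param rates Click rates, Hz (default [click_rate_grid()]).
#' @param count_threshold Crossing threshold, spikes/s (default 110;
#'   distinct from the octopus onset threshold theta).
#' @param refractory Lockout, s (default 1 ms).
#' @param reps Model trials (default 5).
#' @param stage Stage to probe (default `"oct"`).
#' @param seed Master seed.
#' @param dur Train duration, s (default 1).
#' @param level Click level, dB peSPL (default 130).
#' @return A [response_curve()] of kind "clickMTF" with an extra column
#'   `clicks` (clicks presented per second).
#' @export
click_mtf <- function(model, rates = click_rate_grid(),
                      count_threshold = 110, refractory = 1e-3, reps = 5,
                      stage = "oct", seed = 1, dur = 1, level = 130) {
  seeds <- matrix(derive_seeds(seed, length(rates) * reps), nrow = length(rates))
  cps <- numeric(length(rates))
  nclick <- integer(length(rates))
  for (i in seq_along(rates)) {
    w <- make_click_train(rates[i], level = level, dur = dur, fs = model$fs)
    nclick[i] <- max(1L, floor(dur * rates[i] + 1e-9))
    acc <- NULL
    for (r in seq_len(reps)) {
      lam <- simulate_model(model, w, seed = seeds[[i, r]],
                            stages = stage)[[stage]]
      acc <- if (is.null(acc)) lam$lam else acc + lam$lam
    }
    avg <- rate_function(acc / reps, model$fs)
    cps[i] <- count_threshold_crossings(avg, count_threshold, refractory) / dur
  }
  curve <- response_curve(rates, cps, NA_real_, kind = "clickMTF")
  curve$clicks <- nclick / dur
  curve
}

#' Score a rate-velocity function from one trial's rate function
#'
#' For each velocity condition, averages the rate function across that
#' condition's events (aligned to event onsets), locates the peak of the
#' condition average (ties broken by the earliest peak), and integrates a
#' window (default 15 ms) centered at the peak, reporting the mean rate in
#' that window in spikes/s. Events whose analysis segment would run past
#' the end of the record are skipped with a warning.
#'
#' @param lam A [rate_function()] of the response to the chirp sequence.
#' @param events Event data frame from [make_chirp_sequence()].
#' @param window Integration window, s (default 15 ms).
#' @param pad Post-offset padding of the analysis segment, s (default
#'   30 ms, accommodating response latency).
#' @return A [response_curve()] of kind "RVF" (spread `NA`; use [rvf()] for
#'   multi-trial spread).
#' @export
score_rvf <- function(lam, events, window = 0.015, pad = 0.03) {
  if (!is_scalar_num(window) || window <= 0) stop_invalid("`window` must be > 0")
  if (!nrow(events)) stop_invalid("`events` must be non-empty")
  fs <- lam$fs
  n <- length(lam$lam)
  vels <- sort(unique(events$velocity_khz_per_ms))
  k <- max(1L, round(window * fs))
  rate <- vapply(vels, function(v) {
    ev <- events[events$velocity_khz_per_ms == v, ]
    seg_len <- round((max(ev$offset_s - ev$onset_s) + pad) * fs)
    i0 <- round(ev$onset_s * fs) + 1L
    ok <- i0 + seg_len - 1L <= n
    if (!all(ok)) warning("skipping ", sum(!ok),
                          " event(s) extending past the record")
    i0 <- i0[ok]
    if (!length(i0)) return(0)
    avg <- rowMeans(vapply(i0, function(j) lam$lam[j:(j + seg_len - 1L)],
                           numeric(seg_len)))
    p <- which.max(avg)
    lo <- min(max(1L, p - floor(k / 2)), seg_len - k + 1L)
    sum(avg[lo:(lo + k - 1L)]) / fs / window
  }, numeric(1))
  response_curve(vels, rate, kind = "RVF")
}

#' Rate-velocity function of a model stage
#'
#' Builds the aperiodic chirp sequence defined by `spec`, runs `reps`
#' seeded model trials on it, scores each trial with [score_rvf()], and
#' returns mean rate versus signed velocity with the across-trial standard
#' deviation as spread.
#'
#' @param model A [cd_model()].
#' @param spec A [chirp_train_spec()].
#' @param stage Stage to probe (default `"ic"`).
#' @param reps Model trials (default 5).
#' @param window Integration window, s (default 15 ms).
#' @param seed Master seed for the trial front-end noise (the sequence
#'   itself is controlled by `spec$seed`).
#' @return A [response_curve()] of kind "RVF"; the event log is attached as
#'   attribute `"events"`.
#' @export
rvf <- function(model, spec = chirp_train_spec(), stage = "ic", reps = 5,
                window = 0.015, seed = 1) {
  seq_out <- make_chirp_sequence(spec, fs = model$fs)
  seeds <- derive_seeds(seed, reps)
  per_trial <- lapply(seq_len(reps), function(r) {
    lam <- simulate_model(model, seq_out$waveform, seed = seeds[[r]],
                          stages = stage)[[stage]]
    score_rvf(lam, seq_out$events, window = window)$rate
  })
  mat <- do.call(cbind, per_trial)
  vels <- sort(unique(seq_out$events$velocity_khz_per_ms))
  curve <- response_curve(vels, rowMeans(mat),
                          if (reps > 1) apply(mat, 1, sd) else NA_real_,
                          kind = "RVF")
  attr(curve, "events") <- seq_out$events
  curve
}

#' Per-speed direction bias of a rate-velocity function
#'
#' `bias(s) = (R(+s) - R(-s)) / (R(+s) + R(-s))` for every paired speed
#' `s`; positive bias means upward-selective. Defined as 0 when both rates
#' are zero.
#'
#' @param curve A [response_curve()] of kind "RVF" with paired +/- speeds.
#' @return Data frame with columns `speed` and `bias` (in `[-1, 1]`).
#' @export
direction_bias <- function(curve) {
  if (!identical(attr(curve, "kind"), "RVF"))
    stop_invalid("`curve` must be an RVF response curve")
  speeds <- sort(unique(abs(curve$x)))
  up <- curve$rate[match(speeds, curve$x)]
  dn <- curve$rate[match(-speeds, curve$x)]
  if (anyNA(up) || anyNA(dn)) stop_invalid("RVF speeds must be paired +/-")
  tot <- up + dn
  bias <- ifelse(tot == 0, 0, (up - dn) / tot)
  data.frame(speed = speeds, bias = bias)
}

#' Export a response curve as CSV
#' @param curve A [response_curve()].
#' @param path Output file path.
#' @export
write_curve_csv <- function(curve, path) {
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
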