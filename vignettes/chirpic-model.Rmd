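---
title: "A coincidence-detector model of chirp-velocity sensitivity and AM tuning in the inferior colliculus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coincidence-detector model of chirp-velocity sensitivity and AM tuning in the inferior colliculus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chirpic)
```

## The model

Most neurons of the inferior colliculus (IC) are tuned to amplitude
modulation (AM), and most are also sensitive to the direction and velocity
of fast frequency sweeps ("chirps", on the order of kHz/ms). `chirpic`
implements a two-stage phenomenological model that produces both
sensitivities with a small, physiologically interpretable parameter set.

All stages exchange *instantaneous rate functions* $\lambda(t)$ (spikes/s),
the deterministic intensity of an idealized point process, rather than
spike trains. Two coincidence-detector (CD) primitives operate on rate
functions through trailing window integrals
$W_j(t) = \int_{t-\Delta}^{t} \lambda_j(t')\,dt'$:

* **EE (excitatory--excitatory).** A cell requiring all $N$ inputs to be
  active within a window $\Delta$ has output
  $\lambda_{EE}(t) = \sum_l \lambda_l(t) \prod_{j \ne l} W_j(t)$.
  A cell requiring *exactly* $l$ of $N$ sums, over every size-$l$ subset,
  the subset's all-active rate times the complementary survival factor
  $\prod_{j \in \Omega} (1 - W_j(t))$.
* **EI (excitatory--inhibitory).** Inhibition multiplies the excitatory
  rate by a survival factor $(1 - W_{inh}(t))^M$, where the exponent $M$
  counts duplicated, independent inhibitory inputs.

**Octopus-cell stage.** Octopus cells of the posteroventral cochlear
nucleus are onset cells with broad dendritic fields sampling a range of
auditory-nerve (AN) characteristic frequencies (CFs). They behave as
*sequence detectors*: a suprathreshold input preceded by a subthreshold
input is vetoed by the long hyperpolarization that low-voltage-activated
potassium (KL) channels produce after any input. The model realizes this
with `n_cf` identical copies of an on-CF AN input (suprathreshold as a
group) plus one off-CF (OCF) input (subthreshold alone), combined as an
at-least-$(N{-}1)$-of-$N$ EE detector with window `delta_ee`. KL
hyperpolarization is mimicked by survival factors fed by *delayed copies of
the excitatory inputs themselves* (delay `d_hyp`, window `delta_hyp`) —
they are not separate synaptic inputs, so they track exactly the
excitation that causes them. Finally an onset threshold `theta` zeroes all
subthreshold samples, giving the ideal-onset character (a response at tone
onset and entrainment to click trains, but silence during sustained
stimulation). Because a sweep through the two input frequencies sets their
order of arrival, the side of the OCF input determines direction
preference: OCF above CF makes the cell prefer upward chirps, OCF below CF
downward chirps. The alignment delay (`d_cf` *or* `d_ocf`, only one
nonzero) compensates cochlear traveling-wave latency differences.

**IC stage.** The IC neuron receives (i) CF excitation delayed by `d_e`,
(ii) same-frequency inhibition (SFIE): a copy of the CF input delayed by
`d_i > d_e`, window `delta_i`, duplicated `m_i` times — this is the classic
mechanism for band-enhanced (BE) AM tuning, with the excitation–inhibition
delay `d_i - d_e` setting the best modulation frequency (BMF); and (iii)
inhibition from the octopus cell (window `delta_oct`, `m_oct` copies,
delay `d_oct`, default 0, its lead over excitation being realized by
`d_e > 0`). Because the octopus input is itself direction selective, its
*inhibition* imprints the *opposite* direction preference on the IC cell.
The output is half-wave rectified.

## Stimulus battery

All stimuli are calibrated pressure waveforms in pascals (overall level =
RMS re 20 µPa; click levels in peak-equivalent SPL), synthesized at the
model rate (default 100 kHz) and rounded to whole samples:

* **Tones** for response maps: 200 ms, 10-ms raised-cosine ramps, levels
  10–70 dB SPL, frequencies log-spaced 250 Hz–10 kHz.
* **SAM noise** for modulation transfer functions: Gaussian noise
  brick-wall limited to 100 Hz–10 kHz, spectrum level 30 dB SPL, 100%
  sinusoidal modulation, 1 s with 50-ms ramps. The final calibration sets
  the overall level to `spectrum_level + 10 log10(bandwidth)` (70 dB SPL
  for the defaults) after modulation and ramping, so modulated and
  unmodulated references are presented at identical overall level.
* **Aperiodic chirps** for rate-velocity functions (RVFs): each chirp is
  one fundamental period of a Schroeder-phase complex, synthesized directly
  as a linear-frequency cosine sweep between the fundamental $F_0$ and
  16 kHz, where $F_0$ solves $(f_{top}-F_0)F_0 = |v|$ (smaller root; exact
  and bit-reproducible, avoiding any window-excision ambiguity). Duration
  is $1/F_0$; ramps are 10% of duration; level is
  $65 - 10\log_{10}(T/T_{ref})$ dB SPL with $T_{ref}=2.5$ ms, which
  equalizes energy across the twelve velocities
  (±0.40, ±0.80, ±1.59, ±3.16, ±6.24, ±9.24 kHz/ms). The random sequence
  presents every condition exactly `n_reps` times (default 42) in shuffled
  order with uniform 40–60 ms silent gaps (plus a leading and trailing
  gap), under a single seed; the event log records onset, offset and
  velocity for scoring.
* **Click trains**: 0.1-ms rarefaction (negative) pulses, 130 dB peSPL,
  rates 2–900 Hz (the grid extends beyond the 500-Hz convention so the
  entrainment fall-off is visible).

## The surrogate auditory-nerve front-end

The reference front-end for this class of model is a phenomenological AN
model with efferent gain control; reimplementing it is out of scope here.
Instead `chirpic` ships a documented surrogate for high-spontaneous-rate
(HSR) fibers and a backend registry (`register_an_backend()`) whose
adapter contract (waveform + CF in, rate function out) lets any external
AN model drive every routine in the package unchanged.

The surrogate chain, with the reasoning behind each constant:

1. *Causal 4th-order gammatone* at CF, bandwidth $1.019\,\mathrm{ERB}(f)$,
   broadened by $1 + 0.016(L-30)$ above 30 dB SPL — level-dependent
   tuning. Its envelope delay $3/(2\pi b)$ falls from ~6 ms at 500 Hz to
   ~0.2 ms at 10 kHz, reproducing traveling-wave latency differences, the
   raw material for the octopus alignment delays.
2. *Sigmoidal transduction* $s = c^2/(c^2 + c_{50}^2)$ on the compressed
   drive $c = (p/20\,\mu\mathrm{Pa})^{0.3}$, $c_{50} = 100^{0.3}$: a
   threshold foot, ~35 dB sigmoidal dynamic range, and saturation at high
   levels, as for HSR fibers. (Without the Hill foot, tones 60 dB below
   the passband still produce substantial drive and the response map loses
   its tuning.)
3. *6th-order 3-kHz low-pass* (three Butterworth biquads): the steep
   inner-hair-cell membrane filtering that abolishes fine-structure phase
   locking above ~3 kHz while passing envelopes.
4. *Adaptation*: a rapid subtractive term (50% of a 3-ms exponential
   average) and a short-term divisive, gain-control-like term
   ($1 + 4\,\overline{s}_{15\mathrm{ms}}$). The divisive form lets brief
   transients pass at full gain while sustained drive is strongly adapted
   — the behavior that matters downstream, since the octopus EE products
   scale like $\lambda \cdot (\lambda\Delta)^{N-1}$ and need strong, brief
   transients against a modest sustained background.
5. *Scaling*: `rate = spont + 2175 * max(a, 0)`, giving ~60 spikes/s
   spontaneous, ~230 spikes/s sustained for a 70-dB CF tone, and transient
   peaks of 500–900 spikes/s (onset-to-sustained ratio ~2.5–3).

Fiber variability is multiplicative band-limited Gaussian rate noise
(`noise_cv`, default 0.5, low-passed at 1 kHz); a channel is the mean of
`n_fibers = 10` independent realizations, and characterization routines
average and spread over 5 seeded trials (the repetition convention: a
trial's input is a 10-fiber mean, curves report mean ± SD over trials).
Because downstream stages consume rate functions, fibers are rate-noise
realizations, not sampled spike trains; consequences are noted under
*Limitations*.

## Numerical choices

* **Window integrals** use the rectangular rule at the native sample rate,
  with partial sums before one full window, and are **clamped to [0, 1]**.
  The probabilistic reading of $W$ and $1-W$ presumes $\int\lambda\,dt \le
  1$, which realistic AN rates violate over the millisecond windows the
  model needs; clamping is the minimal fix and keeps every survival factor
  a true factor in $[0,1]$. All outputs are therefore nonnegative by
  construction, and the IC half-wave rectification is retained as
  specified even though it never activates under clamping.
* **Delays** round to the nearest whole sample and zero-fill; identical
  input "copies" are the same rate array used $N$ times (the known
  dependence between copies is part of the model's design).
* **RVF scoring** averages the response across a condition's events
  (aligned to onsets, segment = chirp duration + 30 ms for latency),
  locates the peak of the condition average (ties broken earliest), and
  reports the mean rate in a 15-ms window centered there, clamped inside
  the segment. Peaks are located per trial on that trial's condition
  average; the curve reports the across-trial mean and SD.
* **MTF classification**: band-enhanced iff at least 2 contiguous tested
  modulation frequencies reach 1.2× the unmodulated-reference rate
  (band-suppressed dually; both thresholds configurable); BMF is the
  frequency of maximal rate. The criterion is scale invariant. A zero
  unmodulated reference degenerates to "any positive rate counts as
  enhanced".
* **Click MTFs** count upward threshold crossings (110 spikes/s, 1-ms
  refractory lockout) on the *trial-averaged* rate function, since rate
  functions are defined as means over stimulus repetitions; per-trial
  counting double-counts noise wiggles.
* **Fitting** minimizes $1-\mathrm{corr}(RVF_{mod}, RVF_{tem})$ over the
  two free octopus parameters (OCF and the single alignment delay,
  assigned to the higher-CF input) with L-BFGS-B under direction-
  conditional bounds (up: OCF in $[CF, 3CF]$; down: $[CF/3, CF]$; delay
  0–2 ms), best of `n_restarts` random initializations. A zero-variance
  model RVF leaves the correlation undefined; its loss is set to 2 (the
  worst value) so the optimizer is repelled rather than halted. Because
  the bound edge $OCF = CF$ would make the two inputs identical, the inner
  bound is nudged 2% off CF. Finite-difference steps are sized to the
  parameter scales (2% of CF, 0.1 ms) so sample-rounded delays still
  produce usable gradients.

## Parameter presets

Six example neurons ship as presets (`list_presets()`): low (1 kHz),
medium (4 kHz) and high (8 kHz) CF, each in an upward- and a
downward-selective IC variant (the name refers to the IC cell; its octopus
input prefers the opposite direction). Octopus-stage defaults shared by
all presets: `delta_ee` 1 ms, `delta_hyp` 2 ms, `d_hyp` 0.4 ms, `theta`
50 spikes/s; both IC windows are 1 ms; `d_oct = 0`. These values are the
published operating point of the model: EE windows shorter than ~1 ms or
hyperpolarization windows shorter than ~2 ms lose chirp-direction
sensitivity, at the acknowledged cost that the output is no longer a
nonhomogeneous Poisson process.

```{r}
p <- load_preset("cf4k_down")
str(p$octopus)
str(p$ic)
```

## What passing tests do and do not show

The test suite separates four layers. Analytic stimulus laws (chirp
duration/energy, SAM calibration, sequence composition) and the
coincidence algebra (closed forms plus an independent Monte-Carlo Poisson
spike-train oracle that estimates exactly the expected-count products the
algebra defines) are front-end independent. The mechanism layer (sequence
asymmetry, direction flip with the OCF side, IC preference opposite its
octopus input, inhibition monotonicity, BE shaping by `m_i` and
`d_i - d_e`) is demonstrated under the surrogate and should transfer to
any front-end with strong brief transients and CF-dependent latency.
Quantitative worked examples (the entrainment limit in Hz, BMFs of
particular presets in Hz) are front-end *sensitive*: the surrogate
reproduces the trends, and the acceptance script records its actual
numbers; matching the published values exactly requires the reference AN
model through the adapter interface. In particular, under the surrogate
the low-CF upward-selective preset — the weakest, highest-variance example
even in the reference setting — does not show the IC-opposite-octopus
sign, the entrainment plateau ends at 300–400 Hz rather than 600 Hz, and
the high-CF presets' MTF enhancement stays below the 1.2× classification
criterion.

Problem sizes used in the shipped tests (the package's own choice of
routine sizes): mechanism RVFs use 6 presentations per condition at the
full 100-kHz rate with the deterministic front-end; MTF shape tests use
13–25 log-spaced modulation frequencies with 1–2 trials; the acceptance
script uses the full published conditions (42 presentations, 5 trials,
25-point grids) for the quantities it reports.

## Limitations

* The surrogate is not the reference AN model: no efferent gain-control
  dynamics, no medium/low-spontaneous-rate fibers, no species-specific
  tuning, symmetric filter skirts, and rate noise instead of spike
  sampling. Trial-to-trial variability is therefore only qualitatively
  matched; notably the octopus-vs-IC spread ordering of the reference
  model is not reproduced.
* With the long windows the mechanism requires, model outputs are not
  NHPPs, so the framework's statistical-decision-theory threshold
  machinery must not be applied to them; the package does not attempt it.
* Band-suppressed IC types (at least as common as band-enhanced ones in
  physiology) are outside the architecture; they would need an inhibitory
  interneuron stage.
* Binaural inputs and across-CF octopus dendritic cascades are not
  modelled.
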