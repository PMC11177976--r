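# chirpic

Most inferior-colliculus (IC) neurons are rate-tuned to amplitude
modulation (AM), and most are also sensitive to the direction and velocity
of fast frequency sweeps (*chirps*, on the order of kHz/ms) — a feature
absent from standard midbrain models. `chirpic` implements, in R, a
two-stage coincidence-detector model in which both sensitivities coexist:

1. an **octopus-cell stage** (posteroventral cochlear nucleus) that acts as
   a *sequence detector*: `N_CF` copies of an on-CF auditory-nerve input
   and one off-CF input feed an at-least-(N−1)-of-N
   excitatory–excitatory coincidence detector,
   `λ_EE(t) = Σ_l λ_l(t) Π_{j≠l} ∫_{t−Δ}^t λ_j dt'` (summed over the
   exactly-N and exactly-(N−1) terms), multiplied by "hyperpolarization"
   survival factors `(1 − ∫_{t−Δ_Hyp}^t λ dt')` fed by delayed copies of
   the excitatory inputs (standing in for KL-channel dynamics), then
   thresholded at θ into an ideal-onset response. Whether the off-CF
   input lies above or below CF sets the preferred sweep direction;
2. an **IC stage** combining delayed CF excitation, same-frequency
   inhibition (SFIE; delay difference `d_I − d_E` sets the best modulation
   frequency of a band-enhanced MTF) and inhibition from the octopus cell,
   `λ_IC(t) = λ_CF(t−d_E) · (1 − ∫ λ_CF(t−d_I))^{M_I} ·
   (1 − ∫ λ_Oct(t−d_Oct))^{M_Oct}`, half-wave rectified. The octopus
   inhibition imprints the *opposite* direction preference on the IC cell.

The package is for auditory modelers who want to probe how
velocity sensitivity interacts with AM tuning: it synthesizes the full
calibrated stimulus battery (tones, SAM noise, Schroeder-period aperiodic
chirp sequences, click trains), provides a documented surrogate
auditory-nerve front-end with a backend registry for plugging in external
AN models, computes response maps, noise/click modulation transfer
functions and rate-velocity functions (RVFs), ships the six published
example-neuron parameter presets, and fits the octopus free parameters to
step-template RVFs by correlation loss.

## Worked example

Characterize the medium-CF downward-sensitive example neuron (CF 4 kHz,
upward-selective octopus input):

```r
library(chirpic)
m <- preset_model("cf4k_down", fs = 1e5)
#> <cd_model> CF 4000 Hz, OCF 5330 Hz (upward-selective octopus) + IC stage;
#>   fs 100000 Hz, backend 'surrogate'

spec <- chirp_train_spec(n_reps = 8, seed = 1)   # 8 presentations/condition
rv_oct <- rvf(m, spec, stage = "oct", reps = 3, seed = 2)
rv_ic  <- rvf(m, spec, stage = "ic",  reps = 3, seed = 2)
data.frame(velocity = rv_oct$x, oct = round(rv_oct$rate, 1),
           ic = round(rv_ic$rate, 1))
#>    velocity  oct   ic
#> 1     -9.24 19.8 28.5
#> 2     -6.24 13.8 30.0
#> 3     -3.16  9.6 29.2
#> 4     -1.59  3.6 26.8
#> 5     -0.80  0.3 20.8
#> 6     -0.40  2.4 22.3
#> 7      0.40 18.4 21.3
#> 8      0.80 21.0 23.3
#> 9      1.59 25.7 24.6
#> 10     3.16 28.2 24.7
#> 11     6.24 30.8 25.7
#> 12     9.24 31.5 25.9
```

The octopus stage responds far more to upward than to downward chirps
(e.g. 25.7 vs 3.6 spikes/s at ±1.59 kHz/ms); through its inhibition, the
IC cell inherits the opposite (downward) preference, strongest at low
speeds, exactly the layered arrangement the model is built to produce.
The same model's AM tuning:

```r
mt <- noise_mtf(m, fms = mtf_grid(13), reps = 3, stage = "ic", seed = 3)
mt$classification
#> $label
#> [1] "band-enhanced"
#> $bmf
#> [1] 79.4
#> $unmod_rate
#> [1] 5.09
```

— a band-enhanced MTF whose rates exceed the unmodulated reference
(5.1 spikes/s) over a contiguous band, with best modulation frequency
79.4 Hz on this 13-point grid.

`run_experiment(run_config(preset = "cf4k_down", seed = 7, out_dir = "out"))`
runs the whole battery end to end and writes one CSV per curve plus a
metadata sidecar; `inst/cli/chirpic.R` wraps the same calls for the shell
(`preset`, `run`, `stim`, `fit` verbs). `fit_octopus()` optimizes the
off-CF frequency and alignment delay of an octopus cell against an
upward- or downward-step template RVF.

An external auditory-nerve model can replace the built-in surrogate for
every routine via
`register_an_backend("mymodel", function(w, cf, seed, n_avg, ...) ...)`.

## Package layout

- `R/stimuli.R`, `R/waveform.R` — calibrated stimulus synthesis
- `R/an_frontend.R` — surrogate HSR front-end + backend registry
- `R/cd_core.R` — coincidence-detector algebra on rate functions
- `R/octopus_stage.R`, `R/ic_stage.R`, `R/model.R` — the two model stages
- `R/characterization.R` — RM / MTF / click-MTF / RVF procedures
- `R/fitting.R` — template-RVF parameter optimization
- `R/presets.R` — example-neuron presets, YAML configs, experiment driver
- `vignettes/chirpic-model.Rmd` — the methods vignette
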