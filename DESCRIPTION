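Package: chirpic
Title: Coincidence-Detector Model of Chirp-Velocity Sensitivity and
    Amplitude-Modulation Tuning in the Inferior Colliculus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Two-stage coincidence-detector model of auditory midbrain
    responses. A sequence-detecting octopus-cell stage (cochlear nucleus)
    converts the order of arrival of cross-frequency auditory-nerve inputs
    into chirp-direction selectivity; an inferior-colliculus stage combines
    delayed same-frequency inhibition and excitation (SFIE) with inhibition
    from the octopus cell, yielding neurons that are both chirp-velocity
    sensitive and band-enhanced for amplitude modulation. The package
    synthesizes the full calibrated stimulus battery (pure tones,
    sinusoidally amplitude-modulated noise, aperiodic linear-chirp
    sequences derived from Schroeder-phase periods, click trains), provides
    a pluggable auditory-nerve front-end with a documented phenomenological
    surrogate, computes response maps, modulation transfer functions,
    click-entrainment functions and rate-velocity functions, and fits the
    octopus-cell free parameters against step-template rate-velocity
    functions by correlation loss.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
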