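#' Assemble a two-stage coincidence-detector model
#'
#' Binds octopus-cell and IC parameter sets to an auditory-nerve front-end
#' configuration. The resulting object is consumed by [simulate_model()] and
#' by every characterization routine ([response_map()], [noise_mtf()],
#' [click_mtf()], [rvf()]).
#'
#' @param octopus An [octopus_params()].
#' @param ic An [ic_params()], or `NULL` for an octopus-only model.
#' @param fs Model sample rate in Hz (default 100 kHz); stimuli must be
#'   synthesized at this rate.
#' @param backend Auditory-nerve backend name (default `"surrogate"`).
#' @param n_fibers Independent fibers averaged per channel per trial
#'   (default 10).
#' @param spont Fiber spontaneous rate, spikes/s.
#' @param noise_cv Per-fiber rate-noise coefficient passed to the backend;
#'   0 makes trials deterministic.
#' @return An object of class `cd_model`.
#' @export
cd_model <- function(octopus, ic = NULL, fs = 1e5, backend = "surrogate",
                     n_fibers = 10, spont = 60, noise_cv = 0.5) {
  stopifnot(inherits(octopus, "octopus_params"))
  if (!is.null(ic)) stopifnot(inherits(ic, "ic_params"))
  an_backend(backend)  # fail early on unknown backend
  structure(list(octopus = octopus, ic = ic, fs = fs, backend = backend,
                 n_fibers = n_fibers, spont = spont, noise_cv = noise_cv),
            class = "cd_model")
}

#' @export
print.cd_model <- function(x, ...) {
  cat(sprintf(paste0("<cd_model> CF %g Hz, OCF %g Hz (%s-selective octopus)",
                     "%s; fs %g Hz, backend '%s'\n"),
              x$octopus$cf, x$octopus$ocf,
              if (x$octopus$ocf > x$octopus$cf) "upward" else "downward",
              if (is.null(x$ic)) ", octopus stage only" else " + IC stage",
              x$fs, x$backend))
  invisible(x)
}

#' Run the model on a waveform (one trial)
#'
#' Computes the auditory-nerve rate functions of the CF and OCF channels
#' (each the mean of `n_fibers` independent fiber realizations), the
#' octopus-cell stage output and, if configured, the IC stage output. One
#' call is one model trial; characterization routines average several
#' seeded trials.
#'
#' @param model A [cd_model()].
#' @param w A [waveform()] at the model sample rate.
#' @param seed Trial seed (`NULL` = deterministic front-end, no fiber
#'   noise).
#' @param stages Character vector of stages to return, a subset of
#'   `c("an_cf", "an_ocf", "oct", "ic")`.
#' @return Named list of [rate_function()]s.
#' @export
simulate_model <- function(model, w, seed = NULL,
                           stages = c("an_cf", "an_ocf", "oct", "ic")) {
  stopifnot(inherits(model, "cd_model"), inherits(w, "waveform"))
  if (abs(w$fs - model$fs) > 1e-9)
    stop_invalid("waveform sample rate does not match the model sample rate")
  seeds <- derive_seeds(seed, 2L)
  need_ic <- "ic" %in% stages && !is.null(model$ic)
  out <- list()
  an_cf <- an_rate(w, an_channel_spec(model$octopus$cf,
                                      n_fibers = model$n_fibers, n_reps = 1,
                                      spont = model$spont, seed = seeds[[1]]),
                   backend = model$backend, noise_cv = model$noise_cv)
  an_ocf <- an_rate(w, an_channel_spec(model$octopus$ocf,
                                       n_fibers = model$n_fibers, n_reps = 1,
                                       spont = model$spont, seed = seeds[[2]]),
                    backend = model$backend, noise_cv = model$noise_cv)
  oct <- octopus_response(an_cf, an_ocf, model$octopus)
  if ("an_cf" %in% stages) out$an_cf <- an_cf
  if ("an_ocf" %in% stages) out$an_ocf <- an_ocf
  if ("oct" %in% stages) out$oct <- oct
  if (need_ic) out$ic <- ic_response(an_cf, oct, model$ic)
  out
}
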