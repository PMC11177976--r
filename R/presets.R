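# Named parameter presets for the six example neurons (low/medium/high CF,
# upward/downward IC selectivity), YAML run configuration, and the
# end-to-end experiment driver.

# Example-neuron table. Direction refers to the IC cell; its octopus input
# is selective for the opposite direction. Octopus-stage defaults not listed
# per neuron (delta_ee 1 ms, delta_hyp 2 ms, d_hyp 0.4 ms, theta 50) apply
# to all presets.
.preset_table <- list(
  cf1k_down = list(cf = 1000, ocf = 2210, d_cf = 0,       d_ocf = 0.75e-3,
                   n_cf = 4, m_oct = 12, m_i = 8,  d_e = 1.0e-3, d_i = 3.5e-3),
  cf1k_up   = list(cf = 1000, ocf = 900,  d_cf = 1.20e-3, d_ocf = 0,
                   n_cf = 4, m_oct = 12, m_i = 16, d_e = 1.4e-3, d_i = 3.4e-3),
  cf4k_down = list(cf = 4000, ocf = 5330, d_cf = 0.30e-3, d_ocf = 0,
                   n_cf = 3, m_oct = 6,  m_i = 16, d_e = 0.5e-3, d_i = 3.0e-3),
  cf4k_up   = list(cf = 4000, ocf = 2240, d_cf = 1.58e-3, d_ocf = 0,
                   n_cf = 3, m_oct = 6,  m_i = 8,  d_e = 1.5e-3, d_i = 4.0e-3),
  cf8k_down = list(cf = 8000, ocf = 10690, d_cf = 0.21e-3, d_ocf = 0,
                   n_cf = 3, m_oct = 3,  m_i = 8,  d_e = 1.2e-3, d_i = 3.7e-3),
  cf8k_up   = list(cf = 8000, ocf = 5510, d_cf = 0.93e-3, d_ocf = 0,
                   n_cf = 3, m_oct = 12, m_i = 8,  d_e = 1.5e-3, d_i = 4.5e-3))

#' List available example-neuron presets
#' @return Character vector of preset names.
#' @export
list_presets <- function() names(.preset_table)

#' Load an example-neuron preset
#'
#' Returns the exact published parameter values for one of the six example
#' neurons (CF 1, 4 or 8 kHz, upward- or downward-selective IC cell). The
#' direction in the name refers to the IC cell; its octopus-cell input
#' prefers the opposite chirp direction. All presets use Delta_Oct =
#' Delta_I = 1 ms and the octopus-stage defaults (Delta_EE 1 ms, Delta_Hyp
#' 2 ms, d_Hyp 0.4 ms, theta 50 spikes/s).
#'
#' @param name One of `"cf1k_down"`, `"cf1k_up"`, `"cf4k_down"`,
#'   `"cf4k_up"`, `"cf8k_down"`, `"cf8k_up"`.
#' @return A list with elements `name`, `octopus` (an [octopus_params()])
#'   and `ic` (an [ic_params()]).
#' @export
load_preset <- function(name) {
  if (!name %in% names(.preset_table))
    stop("unknown preset: '", name, "' (available: ",
         paste(list_presets(), collapse = ", "), ")", call. = FALSE)
  p <- .preset_table[[name]]
  list(name = name,
       octopus = octopus_params(p$cf, p$ocf, n_cf = p$n_cf,
                                d_cf = p$d_cf, d_ocf = p$d_ocf),
       ic = ic_params(d_e = p$d_e, d_i = p$d_i, m_i = p$m_i,
                      m_oct = p$m_oct))
}

#' Model from a preset
#'
#' Convenience wrapper: [load_preset()] plus [cd_model()].
#' @param name Preset name.
#' @param ... Passed to [cd_model()] (e.g. `fs`, `n_fibers`, `noise_cv`).
#' @export
preset_model <- function(name, ...) {
  p <- load_preset(name)
  cd_model(p$octopus, p$ic, ...)
}

#' Run configuration
#'
#' Bundles everything needed for a reproducible end-to-end run: a preset
#' (or explicit parameter objects), the stimulus battery selection, the
#' master seed and sizing knobs.
#'
#' @param preset Preset name, or `NULL` if `octopus`/`ic` are given.
#' @param octopus,ic Explicit [octopus_params()] / [ic_params()]
#'   (ignored when `preset` is given).
#' @param battery Subset of `c("rm", "mtf", "click", "rvf")`.
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @param fs Model sample rate, Hz.
#' @param reps Model trials per condition.
#' @param backend AN backend name.
#' @param n_fibers,noise_cv Front-end settings.
#' @param rvf_n_reps Chirp presentations per condition (default 42).
#' @param mtf_n,rm_n Grid sizes for the MTF and response map.
#' @return An object of class `run_config`.
#' @export
run_config <- function(preset = NULL, octopus = NULL, ic = NULL,
                       battery = c("rm", "mtf", "click", "rvf"), seed = 1,
                       out_dir = ".", fs = 1e5, reps = 5,
                       backend = "surrogate", n_fibers = 10, noise_cv = 0.5,
                       rvf_n_reps = 42, mtf_n = 25, rm_n = 30) {
  battery <- match.arg(battery, several.ok = TRUE)
  if (is.null(preset)) {
    if (is.null(octopus)) stop_invalid("give `preset` or explicit parameters")
    stopifnot(inherits(octopus, "octopus_params"))
  } else {
    if (!preset %in% list_presets()) stop_invalid("unresolvable preset: ", preset)
  }
  if (is.null(seed)) stop_invalid("`seed` must be set")
  structure(list(preset = preset, octopus = octopus, ic = ic,
                 battery = battery, seed = seed, out_dir = out_dir, fs = fs,
                 reps = reps, backend = backend, n_fibers = n_fibers,
                 noise_cv = noise_cv, rvf_n_reps = rvf_n_reps,
                 mtf_n = mtf_n, rm_n = rm_n),
            class = "run_config")
}

#' Write a run configuration as YAML
#' @param cfg A [run_config()].
#' @param path Output file path.
#' @export
write_run_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$octopus <- if (!is.null(cfg$octopus)) unclass(cfg$octopus)
  x$ic <- if (!is.null(cfg$ic)) unclass(cfg$ic)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML file written by [write_run_config()].
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$octopus)) x$octopus <- do.call(octopus_params, x$octopus)
  if (!is.null(x$ic)) x$ic <- do.call(ic_params, x$ic)
  do.call(run_config, x)
}

#' Run a full characterization experiment
#'
#' Builds the model from the configuration, runs the selected stimulus
#' batteries end to end, and writes one CSV per curve (response map, noise
#' MTF, click MTF, and one RVF per stage) plus a `metadata.json` sidecar
#' carrying the package version, master seed, preset, MTF classification
#' and CF estimate. Deterministic: the same configuration produces
#' byte-identical outputs.
#'
#' @param cfg A [run_config()].
#' @return (Invisibly) a list with the computed objects and output paths.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  pars <- if (!is.null(cfg$preset)) load_preset(cfg$preset)
  else list(name = "custom", octopus = cfg$octopus, ic = cfg$ic)
  model <- cd_model(pars$octopus, pars$ic, fs = cfg$fs,
                    backend = cfg$backend, n_fibers = cfg$n_fibers,
                    noise_cv = cfg$noise_cv)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(paths = character())
  meta <- list(package = "chirpic",
               version = as.character(utils::packageVersion("chirpic")),
               preset = pars$name, seed = cfg$seed, backend = cfg$backend,
               battery = cfg$battery)
  seeds <- derive_seeds(cfg$seed, 4L)
  emit <- function(df, file) {
    p <- file.path(cfg$out_dir, file)
    write.csv(as.data.frame(df), p, row.names = FALSE)
    out$paths <<- c(out$paths, p)
  }
  if ("rm" %in% cfg$battery) {
    out$rm <- response_map(model, freqs = rm_freq_grid(cfg$rm_n),
                           stage = "oct", seed = seeds[[1]])
    emit(out$rm$curves, "response_map.csv")
    meta$cf_estimate_hz <- out$rm$cf
  }
  if ("mtf" %in% cfg$battery) {
    out$mtf <- noise_mtf(model, fms = mtf_grid(cfg$mtf_n), reps = cfg$reps,
                         stage = "ic", seed = seeds[[2]])
    emit(out$mtf$curve, "noise_mtf.csv")
    meta$mtf_classification <- out$mtf$classification
  }
  if ("click" %in% cfg$battery) {
    out$click <- click_mtf(model, reps = cfg$reps, stage = "oct",
                           seed = seeds[[3]])
    emit(out$click, "click_mtf.csv")
  }
  if ("rvf" %in% cfg$battery) {
    spec <- chirp_train_spec(n_reps = cfg$rvf_n_reps, seed = cfg$seed)
    for (stage in c("oct", "ic")) {
      if (stage == "ic" && is.null(model$ic)) next
      curve <- rvf(model, spec, stage = stage, reps = cfg$reps,
                   seed = seeds[[4]])
      out[[paste0("rvf_", stage)]] <- curve
      emit(curve, paste0("rvf_", stage, ".csv"))
    }
  }
  jsonlite::write_json(meta, file.path(cfg$out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  out$paths <- c(out$paths, file.path(cfg$out_dir, "metadata.json"))
  invisible(out)
}
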