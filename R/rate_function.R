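#' Instantaneous discharge-rate function
#'
#' The universal inter-stage currency of the model: a nonnegative
#' instantaneous rate time series lambda(t) in spikes/s at a given sample
#' rate. Auditory-nerve channels, the octopus-cell stage and the IC stage
#' all produce and consume this type.
#'
#' @param lam Numeric vector of instantaneous rate (spikes/s); must be
#'   finite and nonnegative (values within numerical noise of zero are
#'   clamped to 0).
#' @param fs Sample rate in Hz.
#' @return An object of class `rate_function` with fields `lam` and `fs`.
#' @export
rate_function <- function(lam, fs) {
  if (!is_scalar_num(fs) || fs <= 0) stop_invalid("`fs` must be a positive number")
  if (!is.numeric(lam) || anyNA(lam) || any(!is.finite(lam)))
    stop_invalid("`lam` must be finite numeric")
  if (any(lam < -1e-9)) stop_invalid("`lam` must be nonnegative")
  structure(list(lam = pmax(as.numeric(lam), 0), fs = fs),
            class = "rate_function")
}

#' @export
print.rate_function <- function(x, ...) {
  cat(sprintf("<rate_function> %d samples @ %g Hz; mean %.1f, max %.1f spikes/s\n",
              length(x$lam), x$fs, mean(x$lam), max(x$lam)))
  invisible(x)
}

# Check that a list of rate functions share fs and length.
check_aligned <- function(inputs) {
  fs <- vapply(inputs, function(x) x$fs, numeric(1))
  n <- vapply(inputs, function(x) length(x$lam), numeric(1))
  if (length(unique(fs)) != 1L || length(unique(n)) != 1L)
    stop_invalid("rate functions must share sample rate and length")
  invisible(TRUE)
}
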