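#' Construct a sweep (one recorded or simulated trace)
#'
#' A sweep bundles a common time base (ms) with current samples (pA), the
#' voltage command (mV) and protocol metadata. All analysis functions in the
#' package consume and produce sweeps in these canonical units.
#'
#' @param time_ms Time base (ms), strictly increasing.
#' @param current_pA Current samples (pA).
#' @param voltage_mV Voltage command (mV); recycled if scalar.
#' @param meta Named list of metadata (protocol kind, blocker, concentration,
#'   holding voltage, sample rate, seed, units, ...).
#' @param states Optional matrix of state probabilities (rows = states,
#'   columns = samples) attached by the kinetic simulator.
#' @return An object of class `sweep`.
#' @export
new_sweep <- function(time_ms, current_pA, voltage_mV, meta = list(), states = NULL) {
  n <- length(time_ms)
  if (length(voltage_mV) == 1L) voltage_mV <- rep(voltage_mV, n)
  stopifnot(length(current_pA) == n, length(voltage_mV) == n)
  if (n > 1L && any(diff(time_ms) <= 0)) stop("sweep time base must be strictly increasing")
  meta$units <- list(time = "ms", current = "pA", voltage = "mV")
  structure(
    list(
      time_ms = as.numeric(time_ms),
      current_pA = as.numeric(current_pA),
      voltage_mV = as.numeric(voltage_mV),
      meta = meta,
      states = states
    ),
    class = "sweep"
  )
}

#' @export
print.sweep <- function(x, ...) {
  dur <- diff(range(x$time_ms))
  cat(
    sprintf(
      "<sweep> %s | %d samples, %.6g ms | V in [%.6g, %.6g] mV\n",
      x$meta$kind %||% "?", length(x$time_ms), dur,
      min(x$voltage_mV), max(x$voltage_mV)
    )
  )
  invisible(x)
}

#' @export
as.data.frame.sweep <- function(x, ...) {
  data.frame(
    time_ms = x$time_ms,
    current_pA = x$current_pA,
    voltage_mV = x$voltage_mV
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sample_dt <- function(sweep) {
  stats::median(diff(sweep$time_ms))
}
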