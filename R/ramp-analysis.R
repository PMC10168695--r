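#' Current-voltage curve
#'
#' @param voltages Voltages (mV), strictly monotone.
#' @param currents Currents (pA), same length.
#' @param leak_subtracted Logical flag.
#' @param meta Optional metadata list.
#' @return An object of class `iv_curve`.
#' @export
iv_curve <- function(voltages, currents, leak_subtracted = FALSE, meta = list()) {
  stopifnot(length(voltages) == length(currents))
  d <- diff(voltages)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    stop("iv_curve voltages must be strictly monotone")
  }
  structure(
    list(
      voltages = as.numeric(voltages), currents = as.numeric(currents),
      leak_subtracted = isTRUE(leak_subtracted), meta = meta
    ),
    class = "iv_curve"
  )
}

#' Leak-subtract an agonist ramp using its interleaved control
#'
#' Pointwise current difference between matched agonist and control sweeps;
#' the voltage channel is preserved.
#'
#' @param agonist,control Matched [new_sweep()] objects from the same ramp
#'   protocol (same range, speed and sample count to within one sample).
#' @return A leak-subtracted sweep.
#' @export
leak_subtract <- function(agonist, control) {
  stopifnot(inherits(agonist, "sweep"), inherits(control, "sweep"))
  na <- length(agonist$current_pA)
  nc <- length(control$current_pA)
  if (abs(na - nc) > 1) stop("length-mismatch: sweeps differ by more than 1 sample")
  n <- min(na, nc)
  va <- agonist$voltage_mV[seq_len(n)]
  vc <- control$voltage_mV[seq_len(n)]
  if (max(abs(va - vc)) > 1e-6) {
    stop("protocol-mismatch: voltage commands differ between agonist and control")
  }
  meta <- agonist$meta
  meta$leak_subtracted <- TRUE
  new_sweep(
    agonist$time_ms[seq_len(n)],
    agonist$current_pA[seq_len(n)] - control$current_pA[seq_len(n)],
    va,
    meta = meta
  )
}

#' Convert a ramp sweep to an I-V curve
#'
#' @param sweep A ramp [new_sweep()].
#' @return An [iv_curve()] carrying the sweep metadata.
#' @export
sweep_to_iv <- function(sweep) {
  iv_curve(sweep$voltage_mV, sweep$current_pA,
    leak_subtracted = isTRUE(sweep$meta$leak_subtracted), meta = sweep$meta
  )
}

window_indices <- function(voltages, target, window) {
  n <- length(voltages)
  step <- stats::median(abs(diff(voltages)))
  half <- (window - 1) %/% 2
  tol <- (half + 1) * step # a target within half a window of the grid edge is fine
  if (target < min(voltages) - tol || target > max(voltages) + tol) {
    stop("voltage-out-of-range: ", target, " mV not covered by the I-V grid")
  }
  if (window > n) stop("window exceeds record bounds at ", target, " mV")
  centre <- which.min(abs(voltages - target))
  # centre the window on the nearest sample, shifted inward at the edges
  lo <- min(max(centre - half, 1L), n - window + 1L)
  lo:(lo + window - 1L)
}

#' Rectification index from a ramp I-V curve
#'
#' `RI = mean(I over a window centred at v_pos) / |mean(I over a window at
#' v_neg)|`. The numerator keeps its sign, so a linear I-V through 0 mV gives
#' +1 and a fully blocked outward limb gives 0. The windows are `window`
#' consecutive samples centred on the sample nearest each target voltage
#' (15 samples spans about 0.75 mV at 2 kHz and 100 mV/s).
#'
#' @param iv An [iv_curve()], normally leak-subtracted.
#' @param v_pos,v_neg Target voltages (mV).
#' @param window Number of samples per averaging window.
#' @return The rectification index (dimensionless).
#' @export
rectification_index_ramp <- function(iv, v_pos = 60, v_neg = -60, window = 15) {
  stopifnot(inherits(iv, "iv_curve"))
  ip <- mean(iv$currents[window_indices(iv$voltages, v_pos, window)])
  ineg <- mean(iv$currents[window_indices(iv$voltages, v_neg, window)])
  ip / abs(ineg)
}

#' Reversal potential of a leak-subtracted I-V curve
#'
#' Finds the zero crossing of the current within a search window around
#' 0 mV and linearly interpolates between the bracketing samples. A short
#' running-mean smooth (default 15 samples) is applied first so that
#' baseline noise near the reversal does not create spurious crossings; if
#' residual noise still flickers the sign within a narrow (<= 5 mV) band,
#' the root of a least-squares line through that band is returned instead.
#' Sign changes spread over more than 5 mV are a genuine multiple-crossing
#' error.
#'
#' @param iv An [iv_curve()].
#' @param search_half_width Half-width of the voltage search window (mV).
#' @param smooth Samples of running-mean smoothing before crossing detection
#'   (1 = none).
#' @return The reversal potential (mV).
#' @export
reversal_potential <- function(iv, search_half_width = 20, smooth = 15) {
  stopifnot(inherits(iv, "iv_curve"))
  keep <- which(abs(iv$voltages) <= search_half_width)
  if (length(keep) < 2) stop("no-crossing: search window not covered by the I-V grid")
  i <- iv$currents
  if (smooth > 1) {
    i <- stats::filter(i, rep(1 / smooth, smooth), sides = 2)
    i <- as.numeric(i)
  }
  v <- iv$voltages[keep]
  i <- i[keep]
  ok <- is.finite(i)
  v <- v[ok]
  i <- i[ok]
  s <- sign(i)
  cross <- which(s[-1] * s[-length(s)] < 0 | (s[-length(s)] != 0 & s[-1] == 0))
  if (length(cross) == 0) stop("no-crossing: current does not change sign in the search window")
  if (length(cross) == 1) {
    k <- cross[1]
    return(v[k] + (0 - i[k]) * (v[k + 1] - v[k]) / (i[k + 1] - i[k]))
  }
  # residual noise can flicker the sign in a narrow band around the true
  # reversal; take the root of a least-squares line through that band
  span <- diff(range(v[cross]))
  if (span > 5) stop("multiple-crossings: current changes sign more than once in the search window")
  band <- abs(v - stats::median(v[cross])) <= 5
  fit <- stats::lm(i[band] ~ v[band])
  unname(-stats::coef(fit)[1] / stats::coef(fit)[2])
}

#' Conductance-voltage curve
#'
#' @param voltages Voltages (mV).
#' @param conductances Conductances (nS, or dimensionless once normalized).
#' @param v_rev Reversal potential used for the conversion (mV).
#' @param corrected_by_free Whether a polyamine-free reference division was
#'   applied.
#' @param normalized Whether the curve was scaled to 1 at the reference
#'   voltage.
#' @return An object of class `gv_curve`.
#' @export
gv_curve <- function(voltages, conductances, v_rev = NA_real_,
                     corrected_by_free = FALSE, normalized = FALSE) {
  stopifnot(length(voltages) == length(conductances))
  structure(
    list(
      voltages = as.numeric(voltages), conductances = as.numeric(conductances),
      v_rev = v_rev, corrected_by_free = isTRUE(corrected_by_free),
      normalized = isTRUE(normalized)
    ),
    class = "gv_curve"
  )
}

#' Construct a conductance-voltage curve from an I-V curve
#'
#' `G(V) = I(V) / (V - v_rev)`, dropping points within `exclude_mV` of the
#' reversal potential where the driving-force division amplifies noise. If a
#' polyamine-free reference curve is supplied, the conductances are divided
#' by the reference on the common voltage grid, which removes the intrinsic
#' (polyamine-independent) outward rectification and leaves the unblocked
#' fraction. Finally the curve is scaled to 1 at `normalize_at` (default: the
#' most negative retained voltage, where relief of block is maximal).
#'
#' @param iv A leak-subtracted [iv_curve()].
#' @param v_rev Reversal potential (mV), e.g. from [reversal_potential()].
#' @param free_reference Optional [gv_curve()] from the polyamine-free
#'   condition (raw, unnormalized conductances on the same voltage grid).
#' @param normalize_at Voltage (mV) at which the normalized conductance is 1;
#'   `NULL` picks the most negative retained voltage.
#' @param exclude_mV Half-width of the excluded band around `v_rev`.
#' @return A [gv_curve()].
#' @export
conductance_curve <- function(iv, v_rev, free_reference = NULL,
                              normalize_at = NULL, exclude_mV = 5) {
  stopifnot(inherits(iv, "iv_curve"))
  keep <- abs(iv$voltages - v_rev) > exclude_mV
  v <- iv$voltages[keep]
  g <- iv$currents[keep] / (v - v_rev)
  if (!is.null(free_reference)) {
    stopifnot(inherits(free_reference, "gv_curve"))
    m <- match(round(v, 6), round(free_reference$voltages, 6))
    ok <- !is.na(m)
    if (sum(ok) < 6) stop("grid-mismatch: free reference shares too few voltages with the I-V grid")
    v <- v[ok]
    g <- g[ok] / free_reference$conductances[m[ok]]
  }
  if (is.null(normalize_at)) normalize_at <- min(v)
  ref <- which.min(abs(v - normalize_at))
  g <- g / g[ref]
  gv_curve(v, g,
    v_rev = v_rev,
    corrected_by_free = !is.null(free_reference), normalized = TRUE
  )
}

#' Raw (unnormalized) conductance curve, e.g. for use as a free reference
#'
#' @inheritParams conductance_curve
#' @return A [gv_curve()] with raw conductances (nS).
#' @export
raw_conductance_curve <- function(iv, v_rev, exclude_mV = 5) {
  stopifnot(inherits(iv, "iv_curve"))
  keep <- abs(iv$voltages - v_rev) > exclude_mV
  v <- iv$voltages[keep]
  gv_curve(v, iv$currents[keep] / (v - v_rev), v_rev = v_rev)
}
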