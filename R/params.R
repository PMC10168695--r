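#' Blocker parameters for the voltage-dependent block model
#'
#' Describes an intracellular cationic blocker of an AMPAR-like conductance.
#' Block and unblock rates share a symmetric voltage dependence (e-fold factor
#' `2 * h_block` each) so that, for a non-permeant blocker, the equilibrium
#' unblocked fraction is exactly a Boltzmann function of voltage with slope
#' `kb = h_block` and midpoint `Vb = h_block * log(koff0 / (kon0 * concentration))`.
#'
#' @param concentration Blocker concentration (µM).
#' @param kon0 Zero-voltage blocking rate coefficient (µM^-1 ms^-1).
#' @param koff0 Zero-voltage unblocking rate back to the intracellular side (ms^-1).
#' @param kperm0 Zero-voltage permeation rate, i.e. blocker escape to the
#'   extracellular side (ms^-1). Zero for a non-permeant blocker.
#' @param h_block Voltage e-fold factor for block/unblock (mV); equals the
#'   Boltzmann slope factor of the equilibrium block curve.
#' @param h_perm Voltage e-fold factor for permeation (mV).
#' @param closed_block_factor Dimensionless scaling, in `[0, 1]`, of the blocking
#'   rate in non-conducting states (0 = pure open-channel block).
#' @param trap_unblock_rate Unblock rate from the trapped (closed-blocked)
#'   state (ms^-1); its reciprocal sets the slow recovery time constant.
#'
#' @return An object of class `block_params`.
#' @seealso [naspm_params()], [spermine_params()], [equilibrium_unblocked_fraction()]
#' @export
block_params <- function(concentration,
                         kon0,
                         koff0,
                         kperm0 = 0,
                         h_block = 12,
                         h_perm = 25,
                         closed_block_factor = 0,
                         trap_unblock_rate = 2.04e-4) {
  stopifnot(
    is.numeric(concentration), length(concentration) == 1L, is.finite(concentration)
  )
  if (concentration < 0) stop("invalid-parameter: concentration must be >= 0")
  for (nm in c("kon0", "koff0", "kperm0", "closed_block_factor", "trap_unblock_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("invalid-parameter: ", nm, " must be a single non-negative number")
    }
  }
  if (!is.numeric(h_block) || h_block <= 0) stop("invalid-parameter: h_block must be > 0")
  if (!is.numeric(h_perm) || h_perm <= 0) stop("invalid-parameter: h_perm must be > 0")
  if (closed_block_factor > 1) stop("invalid-parameter: closed_block_factor must be in [0, 1]")
  structure(
    list(
      concentration = concentration, kon0 = kon0, koff0 = koff0,
      kperm0 = kperm0, h_block = h_block, h_perm = h_perm,
      closed_block_factor = closed_block_factor,
      trap_unblock_rate = trap_unblock_rate
    ),
    class = "block_params"
  )
}

#' Preset blocker parameter sets
#'
#' `naspm_params()` is a non-permeant open-channel blocker (NASPM-like):
#' IC50 at 0 mV of `koff0 / kon0` = 1 µM and slope factor 12 mV. At 100 µM it
#' produces essentially complete block at +60 mV (unblocked fraction < 1e-4),
#' the full-rectification regime, and at 10 µM the use-dependent regime in
#' which steady-state outward current is suppressed while the early peak is
#' relatively spared. `spermine_params()` is a weakly permeant
#' blocker: depolarization first deepens block, then permeation relieves it,
#' giving a doubly rectifying I-V with an unblocked fraction of about 0.3 at
#' +60 mV (100 µM), the partial-rectification regime.
#'
#' @param concentration Blocker concentration (µM).
#' @param ... Overrides passed on to [block_params()].
#' @return A `block_params` object.
#' @export
naspm_params <- function(concentration = 100, ...) {
  args <- utils::modifyList(
    list(
      concentration = concentration,
      kon0 = 0.0045, koff0 = 0.0045, kperm0 = 0,
      h_block = 12, h_perm = 25,
      closed_block_factor = 0, trap_unblock_rate = 2.04e-4
    ),
    list(...)
  )
  do.call(block_params, args)
}

#' @rdname naspm_params
#' @export
spermine_params <- function(concentration = 100, ...) {
  args <- utils::modifyList(
    list(
      concentration = concentration,
      kon0 = 0.01, koff0 = 0.77, kperm0 = 3.92e-4,
      h_block = 10, h_perm = 6,
      closed_block_factor = 0, trap_unblock_rate = 2.04e-4
    ),
    list(...)
  )
  do.call(block_params, args)
}

#' Receptor gating parameters
#'
#' Ensemble gating of an AMPAR-like conductance: closed (C), open (O) and
#' desensitized (D) states, plus the blocked states added by the block model.
#' The intrinsic, polyamine-independent outward rectification of the open
#' channel is modelled as a multiplicative conductance factor
#' `rho(V) = 1 + exp((V - orect_vhalf) / orect_k)`.
#'
#' The desensitization rate carries a weak voltage dependence,
#' `delta(V) = delta * exp(-V / delta_evolt)`, so that in the absence of
#' blocker the current decay is slightly slower at depolarized potentials
#' (as observed for these receptors); `delta_evolt = Inf` disables it.
#'
#' @param beta Glutamate-bound opening rate (ms^-1).
#' @param alpha Closing rate (ms^-1).
#' @param delta Desensitization rate at 0 mV (ms^-1).
#' @param gamma Recovery-from-desensitization rate (ms^-1).
#' @param delta_evolt e-fold voltage of the desensitization rate (mV).
#' @param g_max Maximal ensemble conductance (nS).
#' @param v_rev Reversal potential (mV).
#' @param orect_vhalf,orect_k Intrinsic outward-rectification factor
#'   parameters (mV); `orect_k` must be non-zero.
#'
#' @return An object of class `gating_params`.
#' @export
gating_params <- function(beta = 10,
                          alpha = 2,
                          delta = 0.165,
                          gamma = 0.0175,
                          delta_evolt = 430,
                          g_max = 10,
                          v_rev = 0,
                          orect_vhalf = 60,
                          orect_k = 35) {
  for (nm in c("beta", "alpha", "delta", "gamma")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("invalid-parameter: ", nm, " must be a single non-negative rate")
    }
  }
  if (!is.numeric(g_max) || g_max <= 0) stop("invalid-parameter: g_max must be > 0")
  if (!is.numeric(orect_k) || orect_k == 0) stop("invalid-parameter: orect_k must be non-zero")
  if (!is.numeric(delta_evolt) || delta_evolt == 0) {
    stop("invalid-parameter: delta_evolt must be non-zero (use Inf to disable)")
  }
  structure(
    list(
      beta = beta, alpha = alpha, delta = delta, gamma = gamma,
      delta_evolt = delta_evolt, g_max = g_max, v_rev = v_rev,
      orect_vhalf = orect_vhalf, orect_k = orect_k
    ),
    class = "gating_params"
  )
}

#' Recording protocol specification
#'
#' @param kind One of `"ramp"`, `"step"`, `"paired_pulse"`, `"mepsc"`, `"evoked"`.
#' @param sample_rate Samples per ms (so 20 = 20 kHz).
#' @param duration Record length (ms). For ramps it is derived from the ramp
#'   range and speed when missing.
#' @param ramp_from,ramp_to Ramp limits (mV).
#' @param ramp_speed Ramp speed (mV/s).
#' @param hold_voltages Holding potential(s) (mV).
#' @param glu_onset Time of glutamate application onset (ms).
#' @param pulse_length Glutamate pulse length (ms).
#' @param inter_pulse_intervals Gaps between the end of one glutamate pulse
#'   and the start of the next (ms), for paired-pulse protocols.
#' @param noise_sd Baseline Gaussian noise standard deviation (pA).
#' @param leak_g Linear leak conductance (nS), reversing at 0 mV.
#' @param seed Integer seed; fixed seed gives bit-reproducible sweeps.
#'
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(kind = c("ramp", "step", "paired_pulse", "mepsc", "evoked"),
                          sample_rate = if (kind == "ramp") 2 else 20,
                          duration = NULL,
                          ramp_from = -80, ramp_to = 60, ramp_speed = 100,
                          hold_voltages = -60,
                          glu_onset = 20, pulse_length = 100,
                          inter_pulse_intervals = c(150, 400, 900, 1900, 3900, 7900),
                          noise_sd = 3.5,
                          leak_g = 1,
                          seed = NULL) {
  kind <- match.arg(kind)
  if (is.null(duration)) {
    duration <- switch(kind,
      ramp = abs(ramp_to - ramp_from) / ramp_speed * 1000,
      step = glu_onset + pulse_length + 50,
      paired_pulse = glu_onset + pulse_length + 50,
      mepsc = 40000,
      evoked = 1000
    )
  }
  stopifnot(sample_rate > 0, duration > 0, noise_sd >= 0)
  structure(
    list(
      kind = kind, sample_rate = sample_rate, duration = duration,
      ramp_from = ramp_from, ramp_to = ramp_to, ramp_speed = ramp_speed,
      hold_voltages = hold_voltages, glu_onset = glu_onset,
      pulse_length = pulse_length,
      inter_pulse_intervals = inter_pulse_intervals,
      noise_sd = noise_sd, leak_g = leak_g, seed = seed
    ),
    class = "protocol_spec"
  )
}

#' Intrinsic outward-rectification factor
#'
#' `rho(V) = 1 + exp((V - orect_vhalf) / orect_k)`; greater than 1 everywhere
#' and increasing with depolarization for positive `orect_k`.
#'
#' @param gating A [gating_params()] object.
#' @param vm Membrane potential(s) (mV).
#' @return Numeric vector of conductance scale factors.
#' @export
orect_factor <- function(gating, vm) {
  1 + exp((vm - gating$orect_vhalf) / gating$orect_k)
}
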