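#' Voltage-dependent block, unblock and permeation rates
#'
#' The bimolecular blocking rate is `kon(V) = kon0 * concentration *
#' exp(V / (2 * h_block))`, the unblocking rate to the intracellular side
#' `koff(V) = koff0 * exp(-V / (2 * h_block))` and the permeation (escape to
#' the extracellular side) rate `kperm(V) = kperm0 * exp(V / h_perm)`.
#' The symmetric split of the block voltage dependence (factor 2) makes the
#' equilibrium block curve an exact Boltzmann for a non-permeant blocker.
#'
#' @param block A [block_params()] object.
#' @param vm Membrane potential(s) (mV).
#' @return A list with numeric vectors `kon`, `koff`, `kperm` (ms^-1).
#' @export
block_rates <- function(block, vm) {
  stopifnot(inherits(block, "block_params"), all(is.finite(vm)))
  list(
    kon = block$kon0 * block$concentration * exp(vm / (2 * block$h_block)),
    koff = block$koff0 * exp(-vm / (2 * block$h_block)),
    kperm = block$kperm0 * exp(vm / block$h_perm)
  )
}

#' Equilibrium unblocked fraction
#'
#' Fraction of open channels not occupied by blocker at steady state:
#' `u(V) = (koff(V) + kperm(V)) / (kon(V) + koff(V) + kperm(V))`.
#' For a non-permeant blocker (`kperm0 = 0`) this reduces exactly to the
#' Boltzmann `1 / (1 + exp((V - Vb) / kb))` with `kb = h_block` and
#' `Vb = h_block * log(koff0 / (kon0 * concentration))`. A permeant blocker
#' adds relief of block at depolarized potentials, so `u(V)` becomes
#' non-monotone (doubly rectifying conductance).
#'
#' @inheritParams block_rates
#' @return Numeric vector of unblocked fractions in `[0, 1]`; 1 wherever no
#'   blocking pathway exists (zero concentration or zero `kon0`).
#' @export
equilibrium_unblocked_fraction <- function(block, vm) {
  r <- block_rates(block, vm)
  den <- r$kon + r$koff + r$kperm
  u <- ifelse(den > 0, (r$koff + r$kperm) / den, 1)
  # no blocking pathway at all: channel is never occupied
  u[r$kon == 0] <- 1
  u
}

#' Boltzmann midpoint of block for a non-permeant blocker
#'
#' `Vb = h_block * log(koff0 / (kon0 * concentration))`, the potential at
#' which half of the open channels are blocked at equilibrium.
#'
#' @inheritParams block_rates
#' @return Midpoint voltage (mV).
#' @export
block_vhalf <- function(block) {
  stopifnot(inherits(block, "block_params"))
  if (block$kon0 <= 0 || block$concentration <= 0 || block$koff0 <= 0) {
    stop("invalid-parameter: Vb is defined only for positive kon0, koff0 and concentration")
  }
  block$h_block * log(block$koff0 / (block$kon0 * block$concentration))
}
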