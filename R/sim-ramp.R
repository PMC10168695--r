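#' Simulate an interleaved voltage-ramp pair (control and agonist)
#'
#' Emulates the steady-state ramp regime (agonist plus cyclothiazide, so
#' desensitization is absent): the control sweep is linear leak plus noise,
#' and the agonist sweep adds the quasi-static receptor current
#' `I(V) = g_max * rho(V) * u(V) * (V - v_rev)`, where `rho(V)` is the
#' intrinsic outward-rectification factor and `u(V)` the
#' [equilibrium_unblocked_fraction()]. Because the ramp is slow relative to
#' blocker equilibration, the open-channel block is treated as at equilibrium
#' at every voltage; accumulation of block during the ramp is not modelled.
#'
#' @inheritParams simulate_step_response
#' @param proto A [protocol_spec()] with `kind = "ramp"`; the voltage runs
#'   linearly from `ramp_from` to `ramp_to` at `ramp_speed` mV/s.
#' @return A list with `control` and `agonist` sweeps.
#' @export
simulate_ramp_pair <- function(gating, block, proto) {
  if (proto$kind != "ramp") stop("protocol-mismatch: proto$kind must be 'ramp'")
  if (!is.null(proto$seed)) set.seed(proto$seed)
  dt <- 1 / proto$sample_rate
  times <- seq(0, proto$duration - dt / 2, by = dt)
  v <- proto$ramp_from + (proto$ramp_to - proto$ramp_from) * times / proto$duration
  leak <- proto$leak_g * v
  u <- equilibrium_unblocked_fraction(block, v)
  rec <- gating$g_max * orect_factor(gating, v) * u * (v - gating$v_rev)
  noise <- function() if (proto$noise_sd > 0) stats::rnorm(length(v), 0, proto$noise_sd) else 0
  meta <- list(
    kind = "ramp", sample_rate = proto$sample_rate,
    ramp_from = proto$ramp_from, ramp_to = proto$ramp_to,
    ramp_speed = proto$ramp_speed,
    concentration_uM = block$concentration, seed = proto$seed
  )
  list(
    control = new_sweep(times, leak + noise(), v, meta = c(meta, list(solution = "control"))),
    agonist = new_sweep(times, leak + rec + noise(), v, meta = c(meta, list(solution = "agonist")))
  )
}
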