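#' Miniature EPSC waveform template
#'
#' Difference-of-exponentials `exp(-t/tau_d) - exp(-t/tau_r)`, normalized to
#' unit peak amplitude.
#'
#' @param t Times since event onset (ms).
#' @param tau_r,tau_d Rise and decay time constants (ms); `tau_r < tau_d`.
#' @return Waveform values, peak value 1.
#' @export
mepsc_template <- function(t, tau_r = 0.2, tau_d = 1.2) {
  if (tau_r >= tau_d) stop("invalid-parameter: tau_r must be < tau_d")
  t_peak <- log(tau_d / tau_r) * tau_r * tau_d / (tau_d - tau_r)
  peak <- exp(-t_peak / tau_d) - exp(-t_peak / tau_r)
  w <- (exp(-t / tau_d) - exp(-t / tau_r)) / peak
  w[t < 0] <- 0
  w
}

#' Simulate a miniature EPSC recording
#'
#' Homogeneous Poisson event times, lognormal per-event amplitudes (defined
#' at -60 mV) and a difference-of-exponentials waveform, on top of white
#' Gaussian baseline noise. At holding potentials other than -60 mV the event
#' amplitude is scaled by `equilibrium_unblocked_fraction(vm) *
#' |(vm - v_rev) / (-60 - v_rev)|` and signed by the driving force, so that a
#' saturating non-permeant blocker suppresses outward events at +60 mV below
#' any realistic detection threshold.
#'
#' @inheritParams simulate_step_response
#' @param proto A [protocol_spec()] with `kind = "mepsc"`; the holding
#'   potential is `proto$hold_voltages[1]` and noise SD `proto$noise_sd`.
#' @param event_rate Mean event frequency (Hz).
#' @param amp_params List with `mean_pA` (mean absolute amplitude at -60 mV),
#'   `cv` (coefficient of variation of the lognormal amplitude distribution),
#'   `tau_r` and `tau_d` (ms).
#' @return A list with `sweep` and `ground_truth`; the latter has
#'   `event_times` (ms), `event_amplitudes_neg` (pA, positive magnitudes at
#'   -60 mV), `true_frequency` (Hz, realized) and `unblocked_fraction_pos`
#'   (the equilibrium unblocked fraction at +60 mV).
#' @export
simulate_mepsc_recording <- function(gating, block, proto, event_rate = 5,
                                     amp_params = list(
                                       mean_pA = 36, cv = 0.3,
                                       tau_r = 0.2, tau_d = 1.2
                                     )) {
  if (proto$kind != "mepsc") stop("protocol-mismatch: proto$kind must be 'mepsc'")
  if (event_rate < 0) stop("invalid-parameter: event_rate must be >= 0")
  if (amp_params$tau_r >= amp_params$tau_d) stop("invalid-parameter: tau_r must be < tau_d")
  if (!is.null(proto$seed)) set.seed(proto$seed)
  vm <- proto$hold_voltages[1]
  dt <- 1 / proto$sample_rate
  n <- floor(proto$duration * proto$sample_rate)
  times <- (seq_len(n) - 1) * dt
  trace <- if (proto$noise_sd > 0) stats::rnorm(n, 0, proto$noise_sd) else numeric(n)

  n_ev <- stats::rpois(1, event_rate * proto$duration / 1000)
  ev_t <- sort(stats::runif(n_ev, 0, proto$duration))
  sdlog <- sqrt(log(1 + amp_params$cv^2))
  meanlog <- log(amp_params$mean_pA) - sdlog^2 / 2
  amps <- stats::rlnorm(n_ev, meanlog, sdlog)

  drive <- (vm - gating$v_rev) / (-60 - gating$v_rev)
  if (isTRUE(all.equal(vm, -60))) {
    scale <- -1 # amplitudes are defined (inward, negative) at -60 mV
  } else {
    scale <- sign(vm - gating$v_rev) *
      equilibrium_unblocked_fraction(block, vm) * abs(drive)
  }

  if (n_ev > 0) {
    wlen <- ceiling(8 * amp_params$tau_d / dt)
    wt <- (0:wlen) * dt
    w <- mepsc_template(wt, amp_params$tau_r, amp_params$tau_d)
    for (k in seq_len(n_ev)) {
      i0 <- floor(ev_t[k] / dt) + 1
      idx <- i0:min(i0 + wlen, n)
      trace[idx] <- trace[idx] + scale * amps[k] * w[seq_along(idx)]
    }
  }

  sweep <- new_sweep(
    times, trace, vm,
    meta = list(
      kind = "mepsc", hold_mV = vm, sample_rate = proto$sample_rate,
      duration_ms = proto$duration, noise_sd = proto$noise_sd,
      concentration_uM = block$concentration, seed = proto$seed
    )
  )
  gt <- list(
    event_times = ev_t,
    event_amplitudes_neg = amps,
    true_frequency = n_ev / (proto$duration / 1000),
    unblocked_fraction_pos = equilibrium_unblocked_fraction(block, 60)
  )
  list(sweep = sweep, ground_truth = gt)
}
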