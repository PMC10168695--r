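test_that("equilibrium unblocked fraction has its closed-form limits", {
  # no blocker: never blocked, at any voltage
  free <- default_free_block()
  expect_equal(equilibrium_unblocked_fraction(free, c(-100, -20, 0, 60, 100)), rep(1, 5))
  expect_equal(equilibrium_unblocked_fraction(naspm_params(0), 60), 1)

  # Boltzmann midpoint identity for a non-permeant blocker
  b <- naspm_params(10)
  vb <- block_vhalf(b)
  expect_equal(equilibrium_unblocked_fraction(b, vb), 0.5, tolerance = 1e-12)

  # exact Boltzmann across the whole voltage range
  v <- seq(-100, 100, by = 5)
  u <- equilibrium_unblocked_fraction(b, v)
  expect_equal(u, 1 / (1 + exp((v - vb) / b$h_block)), tolerance = 1e-12)

  expect_error(block_params(100, kon0 = -1, koff0 = 1), "invalid-parameter")
  expect_error(block_params(-5, kon0 = 1, koff0 = 1), "invalid-parameter")
})

test_that("permeant blocker equilibrium matches the kinetic model's steady state", {
  # long application at fixed voltage: the open-state unblocked fraction
  # O / (O + OB) must relax to the closed-form equilibrium
  g <- gating_params()
  b <- spermine_params(100)
  proto <- protocol_spec("step", duration = 4020, glu_onset = 10, pulse_length = 4000, noise_sd = 0)
  for (vm in c(-60, 0, 60)) {
    sw <- simulate_step_response(g, b, proto, vm)
    st <- sw$states[, max(which(sw$time_ms < 4010)) - 1] # still within the pulse
    u_kin <- st[["O"]] / (st[["O"]] + st[["OB"]])
    expect_equal(u_kin, equilibrium_unblocked_fraction(b, vm), tolerance = 1e-4)
  }
  # permeation keeps the depolarized limit well above zero
  expect_gt(equilibrium_unblocked_fraction(b, 100), 0.3)
})

test_that("equilibrium equivalence holds for the non-permeant blocker at every voltage", {
  g <- gating_params()
  b <- naspm_params(10)
  proto <- protocol_spec("step", duration = 6020, glu_onset = 10, pulse_length = 6000, noise_sd = 0, sample_rate = 2)
  for (vm in seq(-100, 100, by = 25)) {
    sw <- simulate_step_response(g, b, proto, vm)
    st <- sw$states[, max(which(sw$time_ms < 6010)) - 1] # still within the pulse
    u_kin <- st[["O"]] / (st[["O"]] + st[["OB"]])
    expect_equal(u_kin, equilibrium_unblocked_fraction(b, vm), tolerance = 1e-4)
  }
})

test_that("ramp pairs reproduce the three rectification phenotypes", {
  g <- gating_params()
  proto <- protocol_spec("ramp", noise_sd = 0, seed = 1)

  # no blocker: outward rectification, zero current at the reversal potential
  pair <- simulate_ramp_pair(g, default_free_block(), proto)
  iv <- sweep_to_iv(leak_subtract(pair$agonist, pair$control))
  i_at <- function(v) iv$currents[which.min(abs(iv$voltages - v))]
  expect_lt(abs(i_at(g$v_rev)), 1e-9)
  expect_gt(i_at(60) / abs(i_at(-60)), 1) # rho > 1 at positive voltages

  # non-permeant blocker at 100 uM: full inward rectification
  pair_n <- simulate_ramp_pair(g, naspm_params(100), proto)
  iv_n <- sweep_to_iv(leak_subtract(pair_n$agonist, pair_n$control))
  i_n <- function(v) iv_n$currents[which.min(abs(iv_n$voltages - v))]
  expect_lt(abs(i_n(60)) / abs(i_n(-60)), 0.05)

  # permeant blocker: doubly rectifying, interior local minimum in (+10, +60)
  pair_s <- simulate_ramp_pair(g, spermine_params(100), proto)
  iv_s <- sweep_to_iv(leak_subtract(pair_s$agonist, pair_s$control))
  pos <- iv_s$voltages > 10 & iv_s$voltages < 60
  vmin <- iv_s$voltages[pos][which.min(iv_s$currents[pos])]
  expect_gt(vmin, 11)
  expect_lt(vmin, 59)
  imin <- min(iv_s$currents[pos])
  expect_gt(iv_s$currents[which.min(abs(iv_s$voltages - 12))], imin)
  expect_gt(iv_s$currents[which.min(abs(iv_s$voltages - 58))], imin)

  expect_error(simulate_ramp_pair(g, naspm_params(100), protocol_spec("step")), "protocol-mismatch")
})

test_that("step responses decay at the closed-form rate and conserve probability", {
  # alpha << delta regime: decay time constant approaches 1/delta
  g <- gating_params(beta = 20, alpha = 0.01, delta = 0.2, gamma = 0.001, delta_evolt = Inf)
  proto <- protocol_spec("step", noise_sd = 0)
  sw <- simulate_step_response(g, default_free_block(), proto, -60)
  fit <- fit_decay(sw, 1)
  expect_equal(fit$tau_w, 1 / g$delta, tolerance = 0.05)

  # probability conservation at every sample, all protocols
  g2 <- gating_params()
  for (b in list(default_free_block(), naspm_params(10), spermine_params(100))) {
    sw <- simulate_step_response(g2, b, proto, 60)
    expect_lt(max(abs(colSums(sw$states) - 1)), 1e-8)
    expect_gte(min(sw$states), -1e-8)
  }
})

test_that("block accelerates the decay at depolarized potentials only", {
  g <- gating_params()
  b <- naspm_params(10)
  proto <- protocol_spec("step", noise_sd = 0)
  tau_pos <- fit_decay(simulate_step_response(g, b, proto, 60), 1)$tau_w
  tau_neg <- fit_decay(simulate_step_response(g, b, proto, -60), 1)$tau_w
  expect_lt(tau_pos, tau_neg)
})

test_that("time to half block scales inversely with concentration", {
  # pseudo-first-order blocking: kon is proportional to concentration, so
  # doubling the concentration halves the time at which the open-state
  # blocked fraction reaches one half. Gating frozen (channels start open,
  # no closing or desensitization) to isolate the O -> OB relaxation.
  # Oracle: the numerically integrated state trajectories.
  g <- gating_params(beta = 10, alpha = 0, delta = 0, gamma = 0, delta_evolt = Inf)
  proto <- protocol_spec("step", sample_rate = 200, glu_onset = 0, noise_sd = 0)
  t_half <- function(conc) {
    sw <- simulate_step_response(g, naspm_params(conc), proto, 60,
      init_state = c(0, 1, 0, 0, 0)
    )
    blocked <- sw$states["OB", ] / (sw$states["O", ] + sw$states["OB", ])
    idx <- which(blocked >= 0.5)[1]
    sw$time_ms[idx]
  }
  ratio <- t_half(10) / t_half(20)
  expect_equal(ratio, 2, tolerance = 0.02)
})

test_that("pseudo-first-order blocking rate is exactly linear in concentration", {
  r100 <- block_rates(naspm_params(100), 60)$kon
  r10 <- block_rates(naspm_params(10), 60)$kon
  expect_equal(r100 / r10, 10, tolerance = 1e-6)
  # and the Vb-concentration law: -h_block * ln(10) shift per decade
  h <- naspm_params(10)$h_block
  expect_equal(block_vhalf(naspm_params(100)) - block_vhalf(naspm_params(10)),
    -h * log(10),
    tolerance = 1e-12
  )
})

test_that("paired-pulse trains recover fully without blocker and carry state forward", {
  g <- gating_params()
  proto <- protocol_spec("paired_pulse", noise_sd = 0, hold_voltages = -60)
  pairs <- simulate_paired_pulse(g, default_free_block(), proto)
  rc <- recovery_analysis(pairs, fit = FALSE)
  long <- rc$intervals >= 5 / g$gamma
  expect_true(all(rc$ratios[long] > 0.95 & rc$ratios[long] < 1.05))
  # residual desensitization at the shortest interval
  expect_lt(rc$ratios[which.min(rc$intervals)], 1)
  # trapped block at +60 mV: second peaks strongly suppressed at short intervals
  proto60 <- protocol_spec("paired_pulse", noise_sd = 0, hold_voltages = 60)
  rc_b <- recovery_analysis(simulate_paired_pulse(g, naspm_params(10), proto60), fit = FALSE)
  expect_lt(rc_b$ratios[which.min(rc_b$intervals)], 0.5)
  expect_true(all(diff(rc_b$ratios[order(rc_b$intervals)]) > 0))
})

test_that("mEPSC recordings honour rate, suppression and reproducibility", {
  g <- gating_params()
  proto <- protocol_spec("mepsc", duration = 5000, hold_voltages = -60, seed = 42)

  # zero rate: pure noise, empty ground truth
  rec0 <- simulate_mepsc_recording(g, default_free_block(), proto, event_rate = 0)
  expect_length(rec0$ground_truth$event_times, 0)
  expect_equal(sd(rec0$sweep$current_pA), 3.5, tolerance = 0.2)

  # saturating non-permeant blocker at +60 mV: events below 1 pA
  proto_pos <- protocol_spec("mepsc", duration = 10000, hold_voltages = 60, seed = 42)
  rec_b <- simulate_mepsc_recording(g, naspm_params(100), proto_pos, event_rate = 5)
  u <- rec_b$ground_truth$unblocked_fraction_pos
  expect_lt(max(rec_b$ground_truth$event_amplitudes_neg * u), 1)

  # event times strictly increasing; seed reproducibility is bit-exact
  rec1 <- simulate_mepsc_recording(g, default_free_block(), proto, event_rate = 8)
  expect_true(all(diff(rec1$ground_truth$event_times) > 0))
  rec2 <- simulate_mepsc_recording(g, default_free_block(), proto, event_rate = 8)
  expect_identical(rec1$sweep$current_pA, rec2$sweep$current_pA)
  expect_identical(rec1$ground_truth, rec2$ground_truth)

  expect_error(
    simulate_mepsc_recording(g, default_free_block(), proto,
      event_rate = 5,
      amp_params = list(mean_pA = 36, cv = 0.3, tau_r = 2, tau_d = 1)
    ),
    "invalid-parameter"
  )
})

test_that("identical seeds give bit-identical sweeps for every protocol", {
  g <- gating_params()
  b <- naspm_params(10)
  rp <- protocol_spec("ramp", seed = 9)
  expect_identical(
    simulate_ramp_pair(g, b, rp)$agonist$current_pA,
    simulate_ramp_pair(g, b, rp)$agonist$current_pA
  )
  sp <- protocol_spec("step", noise_sd = 2, seed = 9)
  expect_identical(
    simulate_step_response(g, b, sp, -60)$current_pA,
    simulate_step_response(g, b, sp, -60)$current_pA
  )
})
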