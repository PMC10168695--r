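square_sweep <- function(level = -100, base = 0) {
  t <- seq(0, 170, by = 0.05)
  i <- rep(base, length(t))
  i[t >= 20 & t < 120] <- base + level
  new_sweep(t, i, -60, meta = list(kind = "step", glu_onset = 20, pulse_length = 100))
}

test_that("peak and steady-state measurement has its limit behaviours", {
  ps <- peak_and_steady(square_sweep(-100))
  expect_equal(unname(ps), c(-100, -100))

  # zero-current trace
  expect_equal(unname(peak_and_steady(square_sweep(0))), c(0, 0))

  # invariance to a constant baseline offset
  ps_off <- peak_and_steady(square_sweep(-100, base = 37.5))
  expect_equal(ps, ps_off)
})

test_that("steady state matches the closed-form occupancy of the gating scheme", {
  g <- gating_params()
  proto <- protocol_spec("step", noise_sd = 0)
  sw <- simulate_step_response(g, default_free_block(), proto, -60)
  ps <- peak_and_steady(sw)
  expect_lt(abs(ps[["steady"]]), abs(ps[["peak"]]))
  # closed-form steady occupancy of C-O-D at constant glutamate
  delta_v <- g$delta * exp(60 / g$delta_evolt)
  p_o <- 1 / (1 + g$alpha / g$beta + delta_v / g$gamma)
  i_ss <- g$g_max * orect_factor(g, -60) * p_o * (-60 - g$v_rev)
  expect_equal(ps[["steady"]], i_ss, tolerance = 0.02 * abs(i_ss))
})

test_that("exponential decay fits recover known time constants and tau_w", {
  t <- seq(0, 170, by = 0.05)
  mk <- function(i) new_sweep(t, i, -60, meta = list(kind = "step", glu_onset = 20, pulse_length = 100))

  # pure single exponential, tau = 5 ms
  i1 <- ifelse(t >= 20 & t < 120, -80 * exp(-(t - 20) / 5), 0)
  f1 <- fit_decay(mk(i1), 1)
  expect_equal(f1$tau_w, 5, tolerance = 1e-6)

  # direct evaluation of the printed weighted-tau formula
  expect_equal(tau_weighted(75, 2, 25, 10), 4)

  # biexponential trace: amplitudes 75/25, taus 2/10 -> tau_w = 4
  i2 <- ifelse(t >= 20 & t < 120, -(75 * exp(-(t - 20) / 2) + 25 * exp(-(t - 20) / 10)), 0)
  f2 <- fit_decay(mk(i2), 2)
  expect_equal(f2$tau_f, 2, tolerance = 1e-4)
  expect_equal(f2$tau_s, 10, tolerance = 1e-4)
  expect_equal(f2$tau_w, 4, tolerance = 1e-4)

  # a monotonically growing current has no decaying transient to fit
  expect_error(
    fit_decay(mk(ifelse(t >= 20 & t < 120, -80 * (1 - exp(-(t - 20) / 5)), 0)), 1),
    "decay"
  )
})

test_that("noisy biexponential fit is accurate and beats the grid-search oracle", {
  set.seed(77)
  t <- seq(0, 170, by = 0.05)
  decay <- ifelse(t >= 20 & t < 120, -(70 * exp(-(t - 20) / 2.5) + 30 * exp(-(t - 20) / 12)), 0)
  i <- decay + rnorm(length(t), 0, 1)
  sw <- new_sweep(t, i, -60, meta = list(kind = "step", glu_onset = 20, pulse_length = 100))
  f <- fit_decay(sw, 2)
  expect_equal(f$tau_f, 2.5, tolerance = 0.1 * 2.5)
  expect_equal(f$tau_s, 12, tolerance = 0.1 * 12)
  expect_equal(abs(f$a_f), 70, tolerance = 0.1 * 70)

  # SSE floor: amplitudes profiled out over a (tau_f, tau_s) grid
  td <- t[t >= 20 & t < 120]
  pkix <- which.max(-i[t >= 20 & t < 120])
  y <- i[t >= 20 & t < 120][pkix:length(td)]
  tdd <- td[pkix:length(td)] - td[pkix]
  grid_sse <- oracle_biexp_grid_sse(tdd, y, c(0.5, 8), c(5, 40))
  expect_lte(f$rss, grid_sse * (1 + 1e-6))

  # tau_w is always a convex combination of the two time constants
  expect_gte(f$tau_w, min(f$tau_f, f$tau_s))
  expect_lte(f$tau_w, max(f$tau_f, f$tau_s))
})

test_that("decay-voltage profiles reproduce the voltage dependence of block", {
  g <- gating_params()
  proto <- protocol_spec("step", noise_sd = 0)
  volts <- c(10, 30, 50, 70)
  mk_set <- function(block) {
    sw <- lapply(volts, function(vm) simulate_step_response(g, block, proto, vm))
    names(sw) <- volts
    sw
  }
  # positive-limb decays are essentially single-exponential (block dominates)
  prof_b <- decay_voltage_profile(mk_set(naspm_params(10)), n_components = 1)
  expect_true(all(prof_b$ok))
  expect_true(all(diff(prof_b$tau_w_ms) < 0)) # accelerated with depolarization

  # without blocker the decay slows with depolarization
  sw_free <- list(`-60` = simulate_step_response(g, default_free_block(), proto, -60),
                  `60` = simulate_step_response(g, default_free_block(), proto, 60))
  prof_f <- decay_voltage_profile(sw_free)
  expect_gt(prof_f$tau_w_ms[prof_f$voltage_mV == 60], prof_f$tau_w_ms[prof_f$voltage_mV == -60])

  # single voltage: one-row table, no error
  one <- decay_voltage_profile(list(`-60` = sw_free[[1]]))
  expect_identical(nrow(one), 1L)
})

test_that("step-based G-V separates peak and steady-state block", {
  # linear currents: flat unity curve
  v <- seq(-80, 60, by = 20)
  gv <- gv_from_steps(data.frame(voltage_mV = v, current_pA = 2 * v), v_rev = 0)
  expect_equal(gv$conductances, rep(1, length(gv$voltages)), tolerance = 1e-12)

  g <- gating_params()
  proto <- protocol_spec("step", noise_sd = 0)
  volts <- c(-80, -60, -40, -20, 20, 40, 60)
  meas <- lapply(volts, function(vm) {
    ps <- peak_and_steady(simulate_step_response(g, naspm_params(10), proto, vm))
    data.frame(voltage_mV = vm, peak = ps[["peak"]], steady = ps[["steady"]])
  })
  meas <- do.call(rbind, meas)
  gv_peak <- gv_from_steps(data.frame(voltage_mV = meas$voltage_mV, current_pA = meas$peak), 0)
  gv_st <- gv_from_steps(data.frame(voltage_mV = meas$voltage_mV, current_pA = meas$steady), 0)
  at60 <- function(gv) gv$conductances[gv$voltages == 60]
  expect_lt(at60(gv_st), 0.1) # steady-state outward conductance nearly abolished
  expect_gt(at60(gv_peak), 0.2) # peak conductance partially spared
  expect_lt(at60(gv_st), at60(gv_peak) / 4)

  expect_error(gv_from_steps(data.frame(voltage_mV = 0, current_pA = 0), v_rev = 0), "excluded")
})

test_that("recovery analysis resolves the trapped-block slow component", {
  g <- gating_params()

  # identical pulses at a long interval: ratio 1
  proto_l <- protocol_spec("paired_pulse", noise_sd = 0, hold_voltages = -60,
    inter_pulse_intervals = c(3900, 7900)
  )
  rc_l <- recovery_analysis(simulate_paired_pulse(g, default_free_block(), proto_l), fit = FALSE)
  expect_equal(rc_l$ratios, c(1, 1), tolerance = 0.01)

  # +60 mV with blocker: biphasic recovery, slow tau near 1/trap_unblock_rate
  b <- naspm_params(10)
  proto60 <- protocol_spec("paired_pulse", noise_sd = 0, hold_voltages = 60)
  rc_b <- recovery_analysis(simulate_paired_pulse(g, b, proto60))
  expect_true(rc_b$fit_converged)
  expect_equal(rc_b$tau_s, 1 / b$trap_unblock_rate, tolerance = 0.25)
  expect_gt(rc_b$f_s, 0.5)
  expect_lte(rc_b$f_f + rc_b$f_s, 1 + 1e-6)

  # at -60 mV blocker and polyamine-free trains are indistinguishable
  proto_n <- protocol_spec("paired_pulse", noise_sd = 0, hold_voltages = -60)
  r_b <- recovery_analysis(simulate_paired_pulse(g, b, proto_n), fit = FALSE)$ratios
  r_f <- recovery_analysis(simulate_paired_pulse(g, default_free_block(), proto_n), fit = FALSE)$ratios
  expect_lt(max(abs(r_b - r_f)), 0.05)
})

test_that("no-blocker recovery follows the 1/gamma closed form", {
  g <- gating_params()
  proto <- protocol_spec("paired_pulse", noise_sd = 0, hold_voltages = -60,
    inter_pulse_intervals = c(80, 110, 150, 210, 300, 450)
  )
  rc <- recovery_analysis(simulate_paired_pulse(g, default_free_block(), proto), fit = FALSE)
  # log-linear fit of the unrecovered fraction versus interval
  lf <- lm(log(1 - rc$ratios) ~ rc$intervals)
  tau_rec <- -1 / coef(lf)[2]
  expect_equal(unname(tau_rec), 1 / g$gamma, tolerance = 0.10)
})
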