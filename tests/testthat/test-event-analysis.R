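noise_trace <- function(n, sd = 3.5, seed = 1) {
  set.seed(seed)
  rnorm(n, 0, sd)
}

insert_events <- function(x, at_ms, amp, dt = 0.05, tau_r = 0.2, tau_d = 1.2) {
  wlen <- ceiling(8 * tau_d / dt)
  w <- mepsc_template((0:wlen) * dt, tau_r, tau_d)
  for (t0 in at_ms) {
    i0 <- round(t0 / dt) + 1
    idx <- i0:min(i0 + wlen, length(x))
    x[idx] <- x[idx] + amp * w[seq_along(idx)]
  }
  x
}

mk_mepsc_sweep <- function(x, vm = -60, dt = 0.05) {
  new_sweep((seq_along(x) - 1) * dt, x, vm,
    meta = list(kind = "mepsc", hold_mV = vm, sample_rate = 1 / dt)
  )
}

test_that("single-sided Gaussian fit recovers the noise SD", {
  # Monte-Carlo over 100 seeds at 25 kHz, 500 ms
  est <- vapply(1:100, function(s) noise_sd(noise_trace(12500, 3.5, s)), numeric(1))
  expect_lt(abs(mean(est) - 3.5), 0.15)

  # constant trace
  expect_equal(noise_sd(rep(2, 5000)), 0)
  expect_error(noise_sd(mk_mepsc_sweep(rnorm(100)), min_ms = 100), "too short")
})

test_that("single-sided fit resists event contamination where the naive SD fails", {
  x <- noise_trace(10000, 3.5, 5)
  x <- insert_events(x, seq(10, 490, by = 20), amp = -100)
  est <- noise_sd(x, event_polarity = "negative")
  expect_lt(abs(est - 3.5) / 3.5, 0.10)
  expect_gt(sd(x) / 3.5, 1.25)
})

test_that("threshold detection finds inserted events exactly", {
  x <- insert_events(rep(0, 10000), c(100, 200, 300), amp = -30)
  sw <- mk_mepsc_sweep(x)
  tr <- detect_events(sw, threshold = 10)
  expect_identical(nrow(tr$events), 3L)
  expect_true(all(abs(tr$events$time_ms - c(100, 200, 300)) <= 0.4))
  expect_true(all(tr$events$amplitude_pA >= 10))
  expect_true(all(tr$events$monotonic_rise))
  expect_true(all(tr$events$clean_decay))

  # frequency = count / duration
  x12 <- insert_events(rep(0, 40000 / 0.05), seq(1000, 34000, by = 3000), amp = -30)
  tr12 <- detect_events(mk_mepsc_sweep(x12), threshold = 10)
  expect_identical(nrow(tr12$events), 12L)
  expect_equal(tr12$frequency_hz, 0.3)
})

test_that("detection equals the exhaustive threshold-run enumeration oracle", {
  g <- gating_params()
  for (s in c(2, 3, 4)) {
    proto <- protocol_spec("mepsc", duration = 10000, hold_voltages = -60, seed = s)
    rec <- simulate_mepsc_recording(g, default_free_block(), proto, event_rate = 4)
    sigma <- noise_sd(rec$sweep, t_range = c(0, 500))
    thr <- 2.5 * sigma
    tr <- detect_events(rec$sweep, thr)
    processed <- attr(tr, "processed")
    o <- oracle_detect(-processed, thr, dt = 0.05)
    expect_equal(tr$events$time_ms, o$time_ms)
    expect_equal(tr$events$amplitude_pA, o$amplitude)
  }
})

test_that("detection sensitivity: near-perfect recall, almost no false positives", {
  g <- gating_params()
  total_true <- 0
  total_hit <- 0
  total_fp <- 0
  for (s in 11:15) {
    proto <- protocol_spec("mepsc", duration = 20000, hold_voltages = -60, seed = s, noise_sd = 3.5)
    rec <- simulate_mepsc_recording(g, default_free_block(), proto,
      event_rate = 1.5,
      amp_params = list(mean_pA = 36, cv = 0, tau_r = 0.2, tau_d = 1.2)
    )
    tr <- detect_events(rec$sweep, 2.5 * 3.5)
    truth <- rec$ground_truth$event_times
    hit <- vapply(truth, function(t0) any(abs(tr$events$time_ms - t0) < 2), logical(1))
    fp <- vapply(tr$events$time_ms, function(t0) all(abs(truth - t0) > 2), logical(1))
    total_true <- total_true + length(truth)
    total_hit <- total_hit + sum(hit)
    total_fp <- total_fp + sum(fp)
  }
  expect_gte(total_hit / total_true, 0.99)
  expect_lte(total_fp, 1) # spec rate: <= 0.2 per 40 s
})

test_that("record-level QC applies the prorated 10-per-40-s rule", {
  mk_train <- function(n, dur_s) {
    x <- insert_events(rep(0, dur_s * 1000 / 0.05), seq(500, dur_s * 1000 - 500, length.out = n), -30)
    detect_events(mk_mepsc_sweep(x), 10)
  }
  expect_false(qc_record(mk_train(9, 40))$pass)
  expect_true(qc_record(mk_train(10, 40))$pass)
  expect_true(qc_record(mk_train(5, 20))$pass)
})

test_that("event averaging reproduces the template and its rise time", {
  # identical noiseless events: average equals each aligned event exactly
  at <- seq(100, 900, by = 100)
  x <- insert_events(rep(0, 20000), at, amp = -30)
  sw <- mk_mepsc_sweep(x)
  tr <- detect_events(sw, 10, smooth_ms = 0)
  me <- average_events(tr, sw)
  expect_identical(me$n_events, length(at))
  one <- -x[(round(at[1] / 0.05) + 1 - 40):(round(at[1] / 0.05) + 1 + 200)]
  # crossing-aligned average: identical events => identical segments
  i0 <- round(tr$events$time_ms[1] / 0.05) + 1
  seg <- -x[(i0 - 40):(i0 + 200)]
  expect_equal(me$waveform$current_pA, -seg, tolerance = 1e-12)

  # rise time matches direct numeric inversion of the closed-form waveform
  t_at_frac <- function(frac) {
    uniroot(
      function(tt) mepsc_template(tt, 0.2, 1.2) - frac,
      c(1e-6, log(1.2 / 0.2) * 0.2 * 1.2 / 1)
    )$root
  }
  oracle_rise <- t_at_frac(0.8) - t_at_frac(0.2)
  expect_equal(me$rise_20_80_ms, oracle_rise, tolerance = 0.03)

  # contaminated events are excluded from the average
  x2 <- insert_events(rep(0, 20000), c(at, 501), amp = -30) # 501 contaminates 500's decay
  sw2 <- mk_mepsc_sweep(insert_events(x2, 500, amp = -30))
  tr2 <- detect_events(sw2, 10, smooth_ms = 0)
  clean_n <- sum(tr2$events$monotonic_rise & tr2$events$clean_decay)
  expect_lt(clean_n, nrow(tr2$events))
  me2 <- average_events(tr2, sw2)
  expect_identical(me2$n_events, clean_n)
})

test_that("the frequency-weighted rectification index follows its formula", {
  expect_equal(ri_mepsc(20, 5, 20, 5)$ri, 1)
  expect_equal(ri_mepsc(40, 10, 20, 5)$ri, 0.25)
  # zero events at +60: RI = 0 by definition
  expect_equal(ri_mepsc(40, 10, NULL, 0)$ri, 0)
  # no events at -60: undefined
  expect_error(ri_mepsc(NULL, 0, 20, 5), "undefined")
  # scale invariance under a common gain change
  expect_equal(ri_mepsc(13 * 40, 10, 13 * 20, 5)$ri, ri_mepsc(40, 10, 20, 5)$ri)
})

test_that("end-to-end mEPSC regimes give RI = 0 (full block) and 0 < RI < 1 (partial)", {
  g <- gating_params()
  cfg <- default_config(seed = 7)
  cfg$mepsc$duration_ms <- 20000
  full <- polyblock:::mepsc_pipeline(g, naspm_params(100), cfg, 7)
  expect_identical(full$ri$ri, 0)
  part <- polyblock:::mepsc_pipeline(g, spermine_params(100), cfg, 11)
  expect_gt(part$ri$ri, 0)
  expect_lt(part$ri$ri, 1)
  expect_lt(part$train_pos$frequency_hz, part$train_neg$frequency_hz) # event thinning
})

test_that("evoked EPSC analysis computes RI and polynomial I-V fits", {
  dt <- 0.05
  stim <- seq(50, 950, by = 100)
  volts <- c(-80, -60, -40, -20, 20, 40, 60)
  mk <- function(vm, scale) {
    x <- rep(0, 1000 / dt)
    x <- insert_events(x, stim, amp = scale)
    new_sweep((seq_along(x) - 1) * dt, x, vm,
      meta = list(kind = "evoked", hold_mV = vm, sample_rate = 1 / dt)
    )
  }
  # linear synthetic amplitudes
  sw_lin <- lapply(volts, function(v) mk(v, 2 * v))
  names(sw_lin) <- volts
  res <- eepsc_analyze(sw_lin, stim, fit_degree = 1)
  expect_equal(res$ri$ri, 1, tolerance = 1e-9)
  expect_lt(sum(resid(res$iv_fit)^2), 1e-12)

  # saturating non-permeant blocker: outward response abolished
  g <- gating_params()
  b <- naspm_params(100)
  u <- equilibrium_unblocked_fraction(b, volts)
  amp_b <- ifelse(volts < 0, 2 * volts, 2 * volts * u)
  sw_b <- lapply(seq_along(volts), function(i) mk(volts[i], amp_b[i]))
  names(sw_b) <- volts
  res_b <- eepsc_analyze(sw_b, stim, fit_degree = 1)
  expect_lt(res_b$ri$ri, 0.05)

  # doubly rectifying I-V: fifth-order polynomial beats the straight line
  us <- equilibrium_unblocked_fraction(spermine_params(100), volts)
  amp_s <- ifelse(volts < 0, 2 * volts, 2 * volts * us)
  sw_s <- lapply(seq_along(volts), function(i) mk(volts[i], amp_s[i]))
  names(sw_s) <- volts
  r1 <- eepsc_analyze(sw_s, stim, fit_degree = 1)
  r5 <- eepsc_analyze(sw_s, stim, fit_degree = 5)
  expect_lt(sum(resid(r5$iv_fit)^2), sum(resid(r1$iv_fit)^2))
})
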