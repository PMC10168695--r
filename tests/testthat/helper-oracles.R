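# Independent oracles used across the suite. These deliberately re-derive
# results with brute-force or closed-form methods, separate from the package
# code paths they check.

# Exhaustive threshold-run enumeration on a processed trace: every maximal
# run above threshold starts a candidate; a candidate merges into the kept
# predecessor when it is within the refractory gap of it or when the signal
# never fell below the re-arm level in between; the amplitude is the
# extremum within the search window after the crossing.
oracle_detect <- function(s, threshold, dt, refractory_ms = 2,
                          re_arm_fraction = 0.5, search_ms = 10) {
  above <- s > threshold
  starts <- integer()
  for (i in seq_along(s)) {
    if (above[i] && (i == 1 || !above[i - 1])) starts <- c(starts, i)
  }
  gap <- round(refractory_ms / dt)
  re_arm <- re_arm_fraction * threshold
  kept <- integer()
  for (st in starts) {
    if (length(kept) == 0) {
      kept <- st
    } else {
      prev <- kept[length(kept)]
      armed <- min(s[prev:st]) < re_arm
      if (st - prev > gap && armed) kept <- c(kept, st)
    }
  }
  win <- round(search_ms / dt)
  amps <- vapply(kept, function(i0) max(s[i0:min(i0 + win, length(s))]), numeric(1))
  list(time_ms = (kept - 1) * dt, amplitude = amps)
}

# BCa endpoints from an explicitly supplied bootstrap distribution, using
# the documented conventions (Efron z0 with the proportion clamped to
# [1/(B+1), B/(B+1)], jackknife acceleration, type-7 quantiles).
oracle_bca <- function(thetas, theta_hat, jack, conf = 0.95) {
  b <- length(thetas)
  prop <- sum(thetas < theta_hat) / b
  prop <- min(max(prop, 1 / (b + 1)), b / (b + 1))
  z0 <- qnorm(prop)
  jm <- mean(jack)
  a <- sum((jm - jack)^3) / (6 * sum((jm - jack)^2)^1.5)
  alpha <- (1 - conf) / 2
  lims <- sapply(c(qnorm(alpha), qnorm(1 - alpha)), function(z) {
    pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  })
  unname(quantile(thetas, lims, type = 7))
}

# Grid-search SSE floor for a single Boltzmann at fixed Gmax.
oracle_boltzmann_grid_sse <- function(v, g, g_max, vb_range, kb_range, n = 200) {
  vbs <- seq(vb_range[1], vb_range[2], length.out = n)
  kbs <- seq(kb_range[1], kb_range[2], length.out = n)
  best <- Inf
  for (vb in vbs) {
    pred <- outer(v, kbs, function(vv, kb) g_max / (1 + exp((vv - vb) / kb)))
    sse <- colSums((g - pred)^2)
    best <- min(best, min(sse))
  }
  best
}

# Grid-search SSE floor for a biexponential decay: amplitudes and offset are
# profiled out by linear least squares at each (tau_f, tau_s) grid point.
oracle_biexp_grid_sse <- function(t, y, tf_range, ts_range, n = 60) {
  tfs <- seq(tf_range[1], tf_range[2], length.out = n)
  tss <- seq(ts_range[1], ts_range[2], length.out = n)
  best <- Inf
  for (tf in tfs) {
    for (ts in tss) {
      X <- cbind(1, exp(-t / tf), exp(-t / ts))
      fit <- lm.fit(X, y)
      best <- min(best, sum(fit$residuals^2))
    }
  }
  best
}

# Noiseless single-Boltzmann G-V dataset on a voltage grid.
make_boltzmann_gv <- function(vb, kb, g_max = 1, v = seq(-100, 100, by = 10), noise = 0) {
  g <- g_max / (1 + exp((v - vb) / kb))
  if (noise > 0) g <- g + rnorm(length(v), 0, noise)
  gv_curve(v, g, v_rev = 0)
}

default_free_block <- function() block_params(0, 0, 0)
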