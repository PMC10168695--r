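#' Peak and steady-state current of a step response
#'
#' Baseline (mean current before the agonist window) is subtracted; the peak
#' is the extremum of the response sign within the window and the steady
#' state is the mean over the final fraction (default 10%) of the window.
#'
#' @param sweep A [new_sweep()] from a fast-application protocol.
#' @param window Two-element numeric: start and end of the agonist
#'   application (ms). Defaults to the sweep's own `glu_onset` /
#'   `pulse_length` metadata when present.
#' @param steady_fraction Final fraction of the window averaged for the
#'   steady-state level.
#' @return Named numeric vector `c(peak = , steady = )` (pA, baseline
#'   subtracted, signed).
#' @export
peak_and_steady <- function(sweep, window = NULL, steady_fraction = 0.1) {
  stopifnot(inherits(sweep, "sweep"))
  if (is.null(window)) {
    on <- sweep$meta$glu_onset
    if (is.null(on)) stop("window-out-of-range: no window given and no glu_onset metadata")
    window <- c(on, on + sweep$meta$pulse_length)
  }
  t <- sweep$time_ms
  if (window[1] < t[1] || window[2] > t[length(t)] + sample_dt(sweep)) {
    stop("window-out-of-range")
  }
  if (window[1] <= t[1]) stop("baseline overlap: no samples precede the window")
  base_idx <- which(t < window[1])
  win_idx <- which(t >= window[1] & t < window[2])
  baseline <- mean(sweep$current_pA[base_idx])
  y <- sweep$current_pA[win_idx] - baseline
  if (all(y == 0)) {
    return(c(peak = 0, steady = 0))
  }
  # response polarity: sign of the mean deviation during the window
  pol <- sign(mean(y))
  if (pol == 0) pol <- sign(y[which.max(abs(y))])
  peak <- pol * max(pol * y)
  n <- length(win_idx)
  steady_idx <- win_idx[seq.int(max(1L, ceiling(n * (1 - steady_fraction))), n)]
  steady <- mean(sweep$current_pA[steady_idx]) - baseline
  c(peak = peak, steady = steady)
}

#' Amplitude-weighted time constant of a biexponential decay
#'
#' `tau_w = tau_f * Af / (Af + As) + tau_s * As / (Af + As)`.
#'
#' @param a_f,tau_f Fast amplitude and time constant.
#' @param a_s,tau_s Slow amplitude and time constant.
#' @return Weighted time constant (same units as `tau_f`).
#' @export
tau_weighted <- function(a_f, tau_f, a_s, tau_s) {
  tau_f * (a_f / (a_f + a_s)) + tau_s * (a_s / (a_f + a_s))
}

#' Fit the decay of a step-response current with one or two exponentials
#'
#' Fits `I(t) = C + A * exp(-t/tau)` (single) or
#' `I(t) = C + Af * exp(-t/tau_f) + As * exp(-t/tau_s)` (double) from the
#' peak to the end of the agonist window, by Levenberg-Marquardt least
#' squares. The offset `C` absorbs the steady-state level. For the double
#' fit the amplitude-weighted time constant [tau_weighted()] is reported;
#' for the single fit `tau_w = tau`. With `n_components = "auto"` the double
#' model is kept only if an F-test prefers it at `alpha = 0.01`.
#'
#' @param sweep A [new_sweep()].
#' @param n_components 1, 2, or `"auto"`.
#' @param window Agonist window (ms); defaults as in [peak_and_steady()].
#' @param restarts Jittered restarts on non-convergence.
#' @return An object of class `exp_decay_fit` with `n_components`, `a_f`,
#'   `tau_f`, `a_s`, `tau_s`, `offset`, `tau_w`, `rss`, `converged`.
#' @export
fit_decay <- function(sweep, n_components = 2, window = NULL, restarts = 5) {
  stopifnot(inherits(sweep, "sweep"))
  auto <- identical(n_components, "auto")
  if (!auto) stopifnot(n_components %in% c(1, 2))
  if (is.null(window)) {
    on <- sweep$meta$glu_onset
    if (is.null(on)) stop("no window given and no glu_onset metadata")
    window <- c(on, on + sweep$meta$pulse_length)
  }
  t <- sweep$time_ms
  base_idx <- which(t < window[1])
  baseline <- if (length(base_idx)) mean(sweep$current_pA[base_idx]) else 0
  win_idx <- which(t >= window[1] & t < window[2])
  y_all <- sweep$current_pA[win_idx] - baseline
  # response polarity from the extremum (robust when the decay ends near 0)
  pol <- sign(y_all[which.max(abs(y_all))])
  if (pol == 0) pol <- 1
  pk <- which.max(pol * y_all)
  idx <- win_idx[pk:length(win_idx)]
  if (length(idx) < 20) stop("decay segment too short (< 20 samples)")
  td <- t[idx] - t[idx[1]]
  y <- sweep$current_pA[idx] - baseline
  amp0 <- y[1] - y[length(y)]
  if (pol * amp0 <= 0) stop("positive-going decay: no decaying transient from the peak")

  span <- td[length(td)]
  fit1 <- fit_exp_sum(td, y, 1, amp0, span, restarts)
  if (auto || n_components == 2) {
    fit2 <- fit_exp_sum(td, y, 2, amp0, span, restarts)
  }
  use2 <- if (auto) {
    !is.null(fit2) && f_test_prefers(fit1$rss, fit2$rss, length(y), 3, 5, alpha = 0.01)
  } else {
    n_components == 2
  }
  if (use2 && is.null(fit2)) stop("non-convergence: biexponential decay fit failed")
  res <- if (use2) fit2 else fit1
  out <- list(
    n_components = if (use2) 2L else 1L,
    a_f = res$a_f, tau_f = res$tau_f, a_s = res$a_s, tau_s = res$tau_s,
    offset = res$offset,
    tau_w = if (use2) tau_weighted(res$a_f, res$tau_f, res$a_s, res$tau_s) else res$tau_f,
    rss = res$rss, converged = TRUE,
    window = window, n = length(y)
  )
  class(out) <- "exp_decay_fit"
  out
}

f_test_prefers <- function(rss1, rss2, n, p1, p2, alpha = 0.01) {
  if (rss2 >= rss1) return(FALSE)
  f <- ((rss1 - rss2) / (p2 - p1)) / (rss2 / (n - p2))
  stats::pf(f, p2 - p1, n - p2, lower.tail = FALSE) < alpha
}

fit_exp_sum <- function(td, y, k, amp0, span, restarts) {
  dat <- data.frame(td = td, y = y)
  if (k == 1) {
    form <- y ~ C + A * exp(-td / tau)
    start <- list(C = y[length(y)], A = amp0, tau = span / 4)
  } else {
    form <- y ~ C + Af * exp(-td / tf) + As * exp(-td / ts)
    start <- list(
      C = y[length(y)], Af = 0.75 * amp0, tf = span / 10,
      As = 0.25 * amp0, ts = span / 2
    )
  }
  fit <- NULL
  for (attempt in 0:restarts) {
    st <- start
    if (attempt > 0) {
      st <- lapply(st, function(x) x * (1 + stats::rnorm(1, 0, 0.2)) + (x == 0) * stats::rnorm(1, 0, 0.1))
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = st,
        control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-10, ptol = 1e-10)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    if (k == 1) stop("non-convergence: exponential decay fit failed") else return(NULL)
  }
  cf <- as.list(stats::coef(fit))
  if (k == 1) {
    list(a_f = cf$A, tau_f = abs(cf$tau), a_s = NA_real_, tau_s = NA_real_,
      offset = cf$C, rss = sum(stats::resid(fit)^2))
  } else {
    tf <- abs(cf$tf); ts <- abs(cf$ts)
    af <- cf$Af; as_ <- cf$As
    if (tf > ts) { # order components: fast first
      tmp <- tf; tf <- ts; ts <- tmp
      tmp <- af; af <- as_; as_ <- tmp
    }
    list(a_f = af, tau_f = tf, a_s = as_, tau_s = ts,
      offset = cf$C, rss = sum(stats::resid(fit)^2))
  }
}

#' @export
print.exp_decay_fit <- function(x, ...) {
  if (x$n_components == 1) {
    cat(sprintf("<exp_decay_fit: 1 component> tau = %.4g ms (A = %.4g pA)\n", x$tau_f, x$a_f))
  } else {
    cat(sprintf(
      "<exp_decay_fit: 2 components> tau_f = %.4g ms (A %.4g), tau_s = %.4g ms (A %.4g), tau_w = %.4g ms\n",
      x$tau_f, x$a_f, x$tau_s, x$a_s, x$tau_w
    ))
  }
  invisible(x)
}

#' Weighted decay time constant as a function of voltage
#'
#' Runs [fit_decay()] on one sweep per voltage and assembles a table of
#' `tau_w` values. Values from single- and double-exponential fits are pooled
#' into the one `tau_w` column (for a single fit `tau_w = tau`). Per-sweep
#' fit failures are reported as flagged rows, not errors.
#'
#' @param sweeps_by_voltage Named list of sweeps; names are voltages (mV), or
#'   the sweeps carry `hold_mV` metadata.
#' @param n_components Passed to [fit_decay()] (default `"auto"`).
#' @return A data frame with columns `voltage_mV`, `tau_w_ms`,
#'   `n_components`, `ok`.
#' @export
decay_voltage_profile <- function(sweeps_by_voltage, n_components = "auto") {
  stopifnot(length(sweeps_by_voltage) >= 1)
  rows <- lapply(seq_along(sweeps_by_voltage), function(i) {
    sw <- sweeps_by_voltage[[i]]
    vm <- sw$meta$hold_mV %||% as.numeric(names(sweeps_by_voltage)[i])
    fit <- tryCatch(fit_decay(sw, n_components = n_components), error = function(e) NULL)
    if (is.null(fit)) {
      data.frame(voltage_mV = vm, tau_w_ms = NA_real_, n_components = NA_integer_, ok = FALSE)
    } else {
      data.frame(voltage_mV = vm, tau_w_ms = fit$tau_w, n_components = fit$n_components, ok = TRUE)
    }
  })
  out <- do.call(rbind, rows)
  out[order(out$voltage_mV), , drop = FALSE]
}

#' G-V curve from step-response measurements
#'
#' `G = I / (V - v_rev)` for per-voltage peak or steady-state currents,
#' normalized to the most negative voltage; points within `exclude_mV` of the
#' reversal potential are rejected.
#'
#' @param measurements Data frame with columns `voltage_mV` and `current_pA`.
#' @param v_rev Reversal potential (mV).
#' @param exclude_mV Excluded band half-width around `v_rev`.
#' @return A [gv_curve()].
#' @export
gv_from_steps <- function(measurements, v_rev, exclude_mV = 5) {
  v <- measurements$voltage_mV
  i <- measurements$current_pA
  keep <- abs(v - v_rev) > exclude_mV
  if (!any(keep)) stop("all points within the excluded band around v_rev")
  v <- v[keep]
  g <- i[keep] / (v - v_rev)
  o <- order(v)
  v <- v[o]
  g <- g[o]
  g <- g / g[1] # most negative voltage = reference
  gv_curve(v, g, v_rev = v_rev, normalized = TRUE)
}

#' Paired-pulse recovery analysis
#'
#' Computes `Peak2 / Peak1` per inter-pulse interval and, when at least four
#' intervals are available, fits the biexponential recovery model
#' `R(t) = 1 - F_f * exp(-t / tau_f) - F_s * exp(-t / tau_s)` with time
#' constants constrained positive and fractions in `[0, 1]`.
#'
#' @param pairs List of `list(interval_ms, sweep1, sweep2)` as produced by
#'   [simulate_paired_pulse()].
#' @param fit Whether to attempt the biexponential recovery fit.
#' @return An object of class `recovery_curve` with `intervals`, `ratios`,
#'   `voltage`, and (when fitted) `f_f`, `tau_f`, `f_s`, `tau_s`,
#'   `fit_converged`.
#' @export
recovery_analysis <- function(pairs, fit = TRUE) {
  stopifnot(length(pairs) >= 1)
  intervals <- vapply(pairs, function(p) p$interval_ms, numeric(1))
  ratios <- vapply(pairs, function(p) {
    p1 <- peak_and_steady(p$sweep1)[["peak"]]
    p2 <- peak_and_steady(p$sweep2)[["peak"]]
    p2 / p1
  }, numeric(1))
  vm <- pairs[[1]]$sweep1$meta$hold_mV
  out <- list(
    intervals = intervals, ratios = ratios, voltage = vm,
    f_f = NA_real_, tau_f = NA_real_, f_s = NA_real_, tau_s = NA_real_,
    fit_converged = FALSE
  )
  if (fit && length(intervals) >= 4) {
    dat <- data.frame(t = intervals, r = ratios)
    fitobj <- tryCatch(
      minpack.lm::nlsLM(
        r ~ 1 - Ff * exp(-t / tf) - Fs * exp(-t / ts),
        data = dat,
        start = list(Ff = 0.2, tf = min(intervals), Fs = 0.3, ts = max(intervals) / 2),
        lower = c(0, 1e-3, 0, 1e-3), upper = c(1, Inf, 1, Inf),
        control = minpack.lm::nls.lm.control(maxiter = 300)
      ),
      error = function(e) NULL
    )
    if (!is.null(fitobj)) {
      cf <- as.list(stats::coef(fitobj))
      if (cf$tf > cf$ts) cf <- list(Ff = cf$Fs, tf = cf$ts, Fs = cf$Ff, ts = cf$tf)
      out$f_f <- cf$Ff
      out$tau_f <- cf$tf
      out$f_s <- cf$Fs
      out$tau_s <- cf$ts
      out$fit_converged <- TRUE
    }
  }
  class(out) <- "recovery_curve"
  out
}

#' @export
print.recovery_curve <- function(x, ...) {
  cat(sprintf(
    "<recovery_curve> %d intervals at %s mV; ratios %.3g..%.3g",
    length(x$intervals), format(x$voltage), min(x$ratios), max(x$ratios)
  ))
  if (x$fit_converged) {
    cat(sprintf(
      "; fit: F_f %.3g (tau %.4g ms), F_s %.3g (tau %.4g ms)",
      x$f_f, x$tau_f, x$f_s, x$tau_s
    ))
  }
  cat("\n")
  invisible(x)
}
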