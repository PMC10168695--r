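#' Background noise SD from a single-sided Gaussian fit
#'
#' Builds an all-point histogram from a stretch of record (default use: a
#' 500 ms event-free segment at +60 mV) and fits a Gaussian to the half of
#' the distribution on the side away from the event polarity, so that
#' synaptic events contaminating the other tail do not inflate the estimate.
#'
#' @param sweep A [new_sweep()], or a numeric vector of current samples.
#' @param t_range Optional two-element time range (ms) selecting the segment.
#' @param event_polarity `"negative"` (inward events: fit the upper side),
#'   `"positive"`, or `"auto"` (from holding voltage metadata; negative
#'   holding potentials imply inward, i.e. negative, events).
#' @param min_ms Minimum segment length (ms) accepted.
#' @return Fitted noise standard deviation (pA).
#' @export
noise_sd <- function(sweep, t_range = NULL, event_polarity = c("auto", "negative", "positive"),
                     min_ms = 100) {
  event_polarity <- match.arg(event_polarity)
  if (inherits(sweep, "sweep")) {
    x <- sweep$current_pA
    if (!is.null(t_range)) {
      x <- x[sweep$time_ms >= t_range[1] & sweep$time_ms < t_range[2]]
    }
    dur <- length(x) / (sweep$meta$sample_rate %||% (1 / sample_dt(sweep)))
    if (event_polarity == "auto") {
      vm <- sweep$meta$hold_mV %||% stats::median(sweep$voltage_mV)
      event_polarity <- if (vm < 0) "negative" else "positive"
    }
  } else {
    x <- as.numeric(sweep)
    dur <- Inf
    if (event_polarity == "auto") event_polarity <- "negative"
  }
  if (dur < min_ms) stop("segment too short (< ", min_ms, " ms)")
  if (stats::sd(x) == 0) return(0)

  # all-point histogram
  bw <- max(stats::mad(x) / 5, diff(range(x)) / 512)
  breaks <- seq(min(x) - bw, max(x) + bw, by = bw)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  mids <- h$mids
  counts <- h$counts
  mode_x <- mids[which.max(counts)]
  # keep the side away from events (events push counts into their own tail)
  keep <- if (event_polarity == "negative") mids >= mode_x else mids <= mode_x
  dat <- data.frame(x = mids[keep], n = counts[keep])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      n ~ A * exp(-(x - mu)^2 / (2 * sigma^2)),
      data = dat,
      start = list(A = max(counts), mu = mode_x, sigma = stats::mad(x)),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) stop("non-convergence: single-sided Gaussian fit failed")
  abs(stats::coef(fit)[["sigma"]])
}

# Baseline-subtracted, optionally boxcar-smoothed detection trace. Baseline
# is a running median (robust to events); smoothing suppresses white-noise
# threshold crossings at high sampling rates.
preprocess_trace <- function(sweep, baseline_ms = 50, smooth_ms = 0.3) {
  x <- sweep$current_pA
  dt <- sample_dt(sweep)
  k <- round(baseline_ms / dt)
  if (k %% 2 == 0) k <- k + 1
  base <- if (k >= 3 && k < length(x)) stats::runmed(x, k, endrule = "median") else stats::median(x)
  y <- x - base
  ks <- max(1L, round(smooth_ms / dt))
  if (ks > 1) {
    y <- as.numeric(stats::filter(y, rep(1 / ks, ks), sides = 2))
    y[is.na(y)] <- 0
  }
  y
}

#' Detect miniature EPSCs by amplitude threshold crossing
#'
#' The current is baseline-subtracted (running median, `baseline_ms`) and
#' lightly smoothed (`smooth_ms` boxcar), then scanned for crossings of
#' `threshold` in the event polarity. A crossing is merged into the previous
#' candidate when it falls within `refractory_ms` of it, or when the signal
#' has not re-armed (dropped below `re_arm_fraction * threshold`) since the
#' previous candidate — the usual hysteresis rule that stops an event's own
#' decay fluctuating through the threshold from being counted again. The
#' event amplitude is the extremum of the processed trace within `search_ms`
#' after the crossing. Per-event QC flags:
#' `monotonic_rise` is TRUE when no counter-movement larger than one noise SD
#' occurs between crossing and peak; `clean_decay` is TRUE when no new
#' crossing occurs within `5 * tau_d` of the peak.
#'
#' @param sweep A [new_sweep()].
#' @param threshold Detection threshold (pA, positive), typically 2.5 times
#'   the noise SD estimated at +60 mV via [noise_sd()].
#' @param polarity `"auto"` (from holding voltage and reversal), `"negative"`
#'   or `"positive"`.
#' @param noise_sigma Noise SD (pA) used for the monotonic-rise flag;
#'   estimated robustly from the processed trace when `NULL`.
#' @param baseline_ms Running-median baseline window (ms).
#' @param smooth_ms Boxcar smoothing width (ms); 0 disables smoothing.
#' @param refractory_ms Minimum separation between events (ms).
#' @param re_arm_fraction Fraction of the threshold the signal must fall
#'   below before a new event can be registered.
#' @param search_ms Peak search window after each crossing (ms).
#' @param tau_d Nominal event decay time constant (ms) for the clean-decay
#'   flag.
#' @return An object of class `event_train`: data frame `events` (columns
#'   `time_ms`, `amplitude_pA` (absolute), `monotonic_rise`, `clean_decay`)
#'   plus `threshold`, `polarity`, `duration_s`, `frequency_hz`,
#'   `holding_mV`, and the processed trace as attribute `"processed"`.
#' @export
detect_events <- function(sweep, threshold,
                          polarity = c("auto", "negative", "positive"),
                          noise_sigma = NULL,
                          baseline_ms = 50, smooth_ms = 0.3,
                          refractory_ms = 2, re_arm_fraction = 0.5,
                          search_ms = 10, tau_d = 1.2) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(sweep, "sweep"), threshold > 0)
  if (polarity == "auto") {
    vm <- sweep$meta$hold_mV %||% stats::median(sweep$voltage_mV)
    polarity <- if (vm < 0) "negative" else "positive"
  }
  dt <- sample_dt(sweep)
  y <- preprocess_trace(sweep, baseline_ms, smooth_ms)
  s <- if (polarity == "negative") -y else y # events now positive-going
  if (is.null(noise_sigma)) noise_sigma <- stats::mad(diff(s)) / sqrt(2)

  above <- s > threshold
  crossings <- which(above & !c(FALSE, above[-length(above)]))
  dur_s <- length(s) * dt / 1000

  if (length(crossings)) {
    # merge crossings within the refractory gap or before the signal re-arms
    gap <- round(refractory_ms / dt)
    re_arm <- re_arm_fraction * threshold
    kept <- crossings[1]
    for (i0 in crossings[-1]) {
      prev <- kept[length(kept)]
      if (i0 - prev > gap && min(s[prev:i0]) < re_arm) kept <- c(kept, i0)
    }
    crossings <- kept
    win <- round(search_ms / dt)
    n <- length(s)
    ev <- lapply(crossings, function(i0) {
      idx <- i0:min(i0 + win, n)
      pk_rel <- which.max(s[idx])
      pk <- idx[pk_rel]
      amp <- s[pk]
      # monotonic rise: no counter-movement > 1 noise SD from crossing to peak
      seg <- s[i0:pk]
      mono <- if (length(seg) > 1) {
        run_max <- cummax(seg)
        max(run_max - seg) <= noise_sigma
      } else {
        TRUE
      }
      # clean decay: no new crossing within 5 * tau_d of the peak
      dec_end <- min(pk + round(5 * tau_d / dt), n)
      clean <- TRUE
      if (dec_end > pk + 1) {
        post <- s[(pk + 1):dec_end]
        re_above <- post > threshold & !c(s[pk] > threshold, post[-length(post)] > threshold)
        clean <- !any(re_above)
      }
      data.frame(
        time_ms = (i0 - 1) * dt, amplitude_pA = amp,
        monotonic_rise = mono, clean_decay = clean
      )
    })
    events <- do.call(rbind, ev)
  } else {
    events <- data.frame(
      time_ms = numeric(0), amplitude_pA = numeric(0),
      monotonic_rise = logical(0), clean_decay = logical(0)
    )
  }
  out <- list(
    events = events, threshold = threshold, polarity = polarity,
    duration_s = dur_s,
    frequency_hz = nrow(events) / dur_s,
    holding_mV = sweep$meta$hold_mV %||% stats::median(sweep$voltage_mV)
  )
  attr(out, "processed") <- y
  class(out) <- "event_train"
  out
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf(
    "<event_train> %d events in %.3g s (%.3g Hz) at %s mV, threshold %.3g pA\n",
    nrow(x$events), x$duration_s, x$frequency_hz, format(x$holding_mV), x$threshold
  ))
  invisible(x)
}

#' Record-level quality control for mEPSC recordings
#'
#' A recording fails when fewer than `min_events` events were detected at
#' -60 mV per `per_s` seconds of record (rate-prorated for other durations).
#'
#' @param train An [detect_events()] result.
#' @param min_events,per_s The exclusion rule (default: 10 events per 40 s).
#' @return A list with `pass` (logical) and `reason` (string).
#' @export
qc_record <- function(train, min_events = 10, per_s = 40) {
  stopifnot(inherits(train, "event_train"))
  need <- min_events * train$duration_s / per_s
  n <- nrow(train$events)
  if (n < need) {
    list(pass = FALSE, reason = sprintf(
      "%d events in %.3g s (< %g per %g s, prorated %.3g)", n, train$duration_s,
      min_events, per_s, need
    ))
  } else {
    list(pass = TRUE, reason = sprintf("%d events in %.3g s", n, train$duration_s))
  }
}

#' Average clean detected events into a mean waveform
#'
#' Events with both QC flags (`monotonic_rise` and `clean_decay`) are aligned
#' at their threshold-crossing sample and averaged on the processed
#' (baseline-subtracted) trace. The 20-80% rise time and the weighted decay
#' time constant of the average are computed.
#'
#' @param train An [detect_events()] result.
#' @param sweep The sweep the events were detected in.
#' @param pre_ms,post_ms Window around the alignment point (ms).
#' @param decay_components Passed to [fit_decay()] for the average (`"auto"`,
#'   1 or 2).
#' @return An object of class `mean_event`: `waveform` (data frame `time_ms`,
#'   `current_pA`), `n_events`, `peak_abs_pA`, `rise_20_80_ms`, `tau_w_ms`.
#' @export
average_events <- function(train, sweep, pre_ms = 2, post_ms = 10,
                           decay_components = "auto") {
  stopifnot(inherits(train, "event_train"), inherits(sweep, "sweep"))
  ev <- train$events
  ev <- ev[ev$monotonic_rise & ev$clean_decay, , drop = FALSE]
  if (nrow(ev) == 0) stop("no-clean-events: nothing to average")
  y <- attr(train, "processed")
  if (is.null(y)) y <- preprocess_trace(sweep)
  if (train$polarity == "negative") y_al <- -y else y_al <- y
  dt <- sample_dt(sweep)
  pre <- round(pre_ms / dt)
  post <- round(post_ms / dt)
  n <- length(y_al)
  rows <- lapply(ev$time_ms, function(t0) {
    i0 <- round(t0 / dt) + 1
    idx <- (i0 - pre):(i0 + post)
    if (idx[1] < 1 || idx[length(idx)] > n) return(NULL)
    y_al[idx]
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) stop("no-clean-events: all events too close to the record edge")
  avg <- Reduce(`+`, rows) / length(rows)
  # re-baseline on the early pre-window (the running-median baseline is
  # slightly biased near large events)
  base0 <- mean(avg[seq_len(max(1L, pre %/% 2))])
  avg <- avg - base0
  tt <- (seq_along(avg) - 1 - pre) * dt

  pk <- which.max(avg)
  peak_abs <- avg[pk]
  rise <- rise_time_20_80(tt[1:pk], avg[1:pk], peak_abs)

  sign_out <- if (train$polarity == "negative") -1 else 1
  wf <- data.frame(time_ms = tt, current_pA = sign_out * avg)
  avg_sweep <- new_sweep(tt - tt[1], avg, train$holding_mV %||% 0,
    meta = list(kind = "mean_event", glu_onset = tt[pk] - tt[1], pulse_length = post_ms)
  )
  tau_w <- tryCatch(
    fit_decay(avg_sweep,
      n_components = decay_components,
      window = c(tt[pk] - tt[1], tt[length(tt)] - tt[1] + dt)
    )$tau_w,
    error = function(e) NA_real_
  )
  structure(
    list(
      waveform = wf, n_events = length(rows), peak_abs_pA = peak_abs,
      rise_20_80_ms = rise, tau_w_ms = tau_w, polarity = train$polarity
    ),
    class = "mean_event"
  )
}

# 20-80% rise time by linear interpolation on the rising limb
rise_time_20_80 <- function(t, y, peak) {
  t_at <- function(level) {
    above <- which(y >= level)
    if (!length(above)) return(NA_real_)
    i <- above[1]
    if (i == 1) return(t[1])
    t[i - 1] + (level - y[i - 1]) * (t[i] - t[i - 1]) / (y[i] - y[i - 1])
  }
  t80 <- t_at(0.8 * peak)
  t20 <- t_at(0.2 * peak)
  t80 - t20
}

#' @export
print.mean_event <- function(x, ...) {
  cat(sprintf(
    "<mean_event> n = %d, |peak| = %.4g pA, rise 20-80%% = %.3g ms, tau_w = %.3g ms\n",
    x$n_events, x$peak_abs_pA, x$rise_20_80_ms, x$tau_w_ms
  ))
  invisible(x)
}

#' Frequency-weighted mEPSC rectification index
#'
#' `RI = (|mean amplitude at +60| * f_+60) / (|mean amplitude at -60| *
#' f_-60)`. When no events are detected at +60 mV the index is 0 by
#' definition; no events at -60 mV leaves the index undefined (error).
#'
#' @param mean_neg [average_events()] result at -60 mV (required).
#' @param f_neg Event frequency at -60 mV (Hz), > 0.
#' @param mean_pos [average_events()] result at +60 mV, or `NULL` when no
#'   events were detected there.
#' @param f_pos Event frequency at +60 mV (Hz).
#' @return An object of class `rectification_result` with `ri`, per-voltage
#'   components and a mode tag.
#' @export
ri_mepsc <- function(mean_neg, f_neg, mean_pos = NULL, f_pos = 0) {
  if (is.null(mean_neg) || !is.finite(f_neg) || f_neg <= 0) {
    stop("undefined: no events at -60 mV (zero denominator)")
  }
  amp_neg <- abs(if (inherits(mean_neg, "mean_event")) mean_neg$peak_abs_pA else mean_neg)
  if (is.null(mean_pos) || f_pos == 0) {
    ri <- 0
    amp_pos <- 0
  } else {
    amp_pos <- abs(if (inherits(mean_pos, "mean_event")) mean_pos$peak_abs_pA else mean_pos)
    ri <- (amp_pos * f_pos) / (amp_neg * f_neg)
  }
  structure(
    list(
      ri = ri, mode = "mepsc",
      components = data.frame(
        voltage_mV = c(-60, 60),
        mean_amp_pA = c(amp_neg, amp_pos),
        frequency_hz = c(f_neg, f_pos)
      )
    ),
    class = "rectification_result"
  )
}

#' @export
print.rectification_result <- function(x, ...) {
  cat(sprintf("<rectification_result: %s> RI(+60/-60) = %.4g\n", x$mode, x$ri))
  invisible(x)
}

#' Evoked EPSC averaging, rectification and I-V fit
#'
#' Builds stimulus-aligned average waveforms per holding voltage, measures
#' their absolute peaks, computes `RI = |peak(+60)| / |peak(-60)|`, and fits
#' the normalized peak I-V with a straight line or a fifth-order polynomial.
#'
#' @param sweeps_by_voltage Named list of sweeps (one or more per voltage;
#'   names or `hold_mV` metadata give the voltage).
#' @param stim_times Stimulus times (ms), common to all sweeps.
#' @param window_ms Response window after each stimulus (ms).
#' @param baseline_ms Pre-stimulus baseline length (ms).
#' @param fit_degree 1 (straight line) or 5 (fifth-order polynomial).
#' @return A list with `means` (per-voltage average waveforms and peaks),
#'   `ri` (a `rectification_result`), and `iv_fit` (`lm` object on the
#'   normalized peak I-V).
#' @export
eepsc_analyze <- function(sweeps_by_voltage, stim_times, window_ms = 20,
                          baseline_ms = 5, fit_degree = 1) {
  stopifnot(length(sweeps_by_voltage) >= 1, fit_degree %in% c(1, 5))
  volts <- vapply(seq_along(sweeps_by_voltage), function(i) {
    sweeps_by_voltage[[i]]$meta$hold_mV %||% as.numeric(names(sweeps_by_voltage)[i])
  }, numeric(1))
  uv <- sort(unique(volts))
  means <- lapply(uv, function(vm) {
    sws <- sweeps_by_voltage[volts == vm]
    segs <- list()
    for (sw in sws) {
      dt <- sample_dt(sw)
      pre <- round(baseline_ms / dt)
      post <- round(window_ms / dt)
      for (t0 in stim_times) {
        i0 <- round(t0 / dt) + 1
        idx <- (i0 - pre):(i0 + post)
        if (idx[1] < 1 || idx[length(idx)] > length(sw$current_pA)) next
        seg <- sw$current_pA[idx]
        segs[[length(segs) + 1]] <- seg - mean(seg[1:pre])
      }
    }
    if (!length(segs)) stop("no stimulus-locked windows inside the record at ", vm, " mV")
    avg <- Reduce(`+`, segs) / length(segs)
    pk <- avg[which.max(abs(avg))]
    list(voltage = vm, waveform = avg, n = length(segs), peak_pA = pk)
  })
  peaks <- vapply(means, function(m) m$peak_pA, numeric(1))
  ipos <- which(uv == 60)
  ineg <- which(uv == -60)
  if (!length(ipos) || !length(ineg)) stop("missing +60 or -60 mV data for RI")
  ri <- structure(
    list(
      ri = abs(peaks[ipos]) / abs(peaks[ineg]), mode = "eepsc",
      components = data.frame(voltage_mV = uv, peak_pA = peaks)
    ),
    class = "rectification_result"
  )
  norm <- peaks / abs(peaks[ineg])
  iv_fit <- stats::lm(norm ~ stats::poly(uv, fit_degree, raw = TRUE))
  list(means = means, ri = ri, iv_fit = iv_fit)
}
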